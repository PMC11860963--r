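#' Task configuration for the prosocial reversal bandit
#'
#' Describes the structure of the Prosocial Reinforcement Learning Task
#' (PRLT): two interleaved two-armed bandit problems, one rewarding the
#' participant ("self"), one rewarding another person ("other"). Within each
#' condition one arm carries the high reward probability and the other the low
#' one; the assignment swaps every `reversal_period` within-condition trials.
#'
#' @param n_blocks Number of task blocks (default 3).
#' @param trials_per_condition Trials per condition per block (default 30), so
#'   a block has `2 * trials_per_condition` presentations.
#' @param p_high,p_low Reward probabilities of the currently high / low arm
#'   (defaults 0.70 / 0.30). Must satisfy `0 <= p_low < p_high <= 1`.
#' @param reversal_period Within-condition trials between probability swaps
#'   (default 10).
#' @param response_window Response deadline in seconds; metadata only, not
#'   used by the simulator (default 4).
#' @param first_condition Condition shown on the first trial of each block,
#'   `"self"` or `"other"`.
#'
#' @return A validated list of class `prlt_task_config`.
#' @examples
#' cfg <- task_config(trials_per_condition = 10)
#' build_schedule(cfg)
#' @export
task_config <- function(n_blocks = 3, trials_per_condition = 30,
                        p_high = 0.70, p_low = 0.30, reversal_period = 10,
                        response_window = 4,
                        first_condition = c("self", "other")) {
  first_condition <- match.arg(first_condition)
  stop_unless(is_count(n_blocks) && n_blocks >= 1, "n_blocks must be a positive integer")
  stop_unless(is_count(trials_per_condition) && trials_per_condition >= 1,
              "trials_per_condition must be a positive integer")
  stop_unless(is_count(reversal_period) && reversal_period >= 1,
              "reversal_period must be a positive integer")
  stop_unless(is.numeric(p_high) && is.numeric(p_low) && length(p_high) == 1 &&
                length(p_low) == 1 && p_low >= 0 && p_high <= 1,
              "p_low and p_high must be probabilities")
  stop_unless(p_low < p_high, "p_low must be strictly smaller than p_high")
  stop_unless(is.numeric(response_window) && response_window > 0,
              "response_window must be a positive number of seconds")
  structure(
    list(n_blocks = as.integer(n_blocks),
         trials_per_condition = as.integer(trials_per_condition),
         p_high = p_high, p_low = p_low,
         reversal_period = as.integer(reversal_period),
         response_window = response_window,
         first_condition = first_condition),
    class = "prlt_task_config")
}

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x == round(x)

stop_unless <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

#' Build the deterministic trial schedule
#'
#' Expands a [task_config()] into one row per trial. Conditions strictly
#' alternate within a block; reversal times are fixed by `reversal_period`
#' (the high arm flips after within-condition trials `reversal_period`,
#' `2 * reversal_period`, ...), so the schedule contains no randomness. Arm
#' "a" starts as the high arm in every condition and block.
#'
#' @param config A `prlt_task_config`, see [task_config()].
#' @return A tibble of class `prlt_schedule` with columns `block`,
#'   `trial_in_block`, `condition`, `within_condition_index`, `p_arm_a`,
#'   `p_arm_b`, `high_arm`; the config is kept in the `"config"` attribute.
#' @export
build_schedule <- function(config = task_config()) {
  stopifnot(inherits(config, "prlt_task_config"))
  n_per <- config$trials_per_condition
  conds <- if (config$first_condition == "self") c("self", "other") else c("other", "self")
  block_tbl <- tibble::tibble(
    trial_in_block = seq_len(2L * n_per),
    condition = rep(conds, n_per),
    within_condition_index = rep(seq_len(n_per), each = 2L)
  )
  # phase 1 (trials 1..reversal_period) has arm a high, then alternates
  phase <- (ceiling(block_tbl$within_condition_index / config$reversal_period) - 1L) %% 2L
  block_tbl$high_arm <- ifelse(phase == 0L, "a", "b")
  block_tbl$p_arm_a <- ifelse(block_tbl$high_arm == "a", config$p_high, config$p_low)
  block_tbl$p_arm_b <- ifelse(block_tbl$high_arm == "a", config$p_low, config$p_high)

  out <- dplyr::bind_rows(
    lapply(seq_len(config$n_blocks), function(b) dplyr::mutate(block_tbl, block = b)))
  out <- dplyr::select(out, "block", "trial_in_block", "condition",
                       "within_condition_index", "p_arm_a", "p_arm_b", "high_arm")
  new_schedule(out, config)
}

new_schedule <- function(tbl, config) {
  structure(tibble::as_tibble(tbl),
            config = config,
            class = c("prlt_schedule", class(tibble::tibble())))
}

#' @export
print.prlt_schedule <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<prlt_schedule: %d block(s) x 2 x %d trials, p = %.2f/%.2f, reversal every %d>\n",
              cfg$n_blocks, cfg$trials_per_condition, cfg$p_high, cfg$p_low,
              cfg$reversal_period))
  NextMethod()
}

#' Write or read a schedule as a plain trial table
#'
#' The on-disk format is a comma-separated file mirroring the schedule
#' columns, with 1-based block and trial indices; a schedule survives the
#' round trip unchanged.
#'
#' @param x A `prlt_schedule`.
#' @param path File path.
#' @return `read_schedule()` returns a `prlt_schedule`; `write_schedule()`
#'   returns `x` invisibly.
#' @export
write_schedule <- function(x, path) {
  stopifnot(inherits(x, "prlt_schedule"))
  readr::write_csv(tibble::as_tibble(unclass_schedule(x)), path)
  invisible(x)
}

unclass_schedule <- function(x) {
  attr(x, "config") <- NULL
  class(x) <- class(tibble::tibble())
  x
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  tbl <- readr::read_csv(path, col_types = readr::cols(
    block = readr::col_integer(),
    trial_in_block = readr::col_integer(),
    condition = readr::col_character(),
    within_condition_index = readr::col_integer(),
    p_arm_a = readr::col_double(),
    p_arm_b = readr::col_double(),
    high_arm = readr::col_character()))
  cfg <- infer_config(tbl)
  new_schedule(tbl, cfg)
}

# Reconstruct the generating config from a schedule table; reversal period is
# recovered from the first flip of high_arm (or the run length when no flip).
infer_config <- function(tbl) {
  one_cond <- tbl[tbl$block == tbl$block[1] & tbl$condition == tbl$condition[1], ]
  flips <- which(diff(match(one_cond$high_arm, c("a", "b"))) != 0)
  rev_period <- if (length(flips)) flips[1] else nrow(one_cond)
  task_config(
    n_blocks = length(unique(tbl$block)),
    trials_per_condition = nrow(one_cond),
    p_high = max(tbl$p_arm_a, tbl$p_arm_b), p_low = min(tbl$p_arm_a, tbl$p_arm_b),
    reversal_period = rev_period,
    first_condition = tbl$condition[1])
}
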