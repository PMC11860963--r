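#' Default cell means and block-2 shifts for cohort generation
#'
#' One row per observation-group x subtype cell, giving the block-1
#' population means of the four separate-parameter values and the additive
#' block-2 shifts of the two learning rates. Block 3 reuses the block-1
#' parameters (the manipulation is removed). Defaults encode the planted
#' "audience" effect: selfish subjects under observation raise their
#' other-regarding learning rate (+0.25) and lower their self-regarding one
#' (-0.15) in block 2; all other cells are unshifted. Baseline means give
#' selfish subjects `alpha_self > alpha_other` and prosocial subjects the
#' reverse, with self inverse temperatures slightly higher than other.
#'
#' @return A tibble with columns `group`, `subtype`, `alpha_self`,
#'   `alpha_other`, `tau_self`, `tau_other`, `d_alpha_self_b2`,
#'   `d_alpha_other_b2`.
#' @export
default_effect_table <- function() {
  tidyr::expand_grid(group = c("OBS", "CON"),
                     subtype = c("selfish", "prosocial")) |>
    dplyr::mutate(
      alpha_self = ifelse(.data$subtype == "selfish", 0.50, 0.30),
      alpha_other = ifelse(.data$subtype == "selfish", 0.25, 0.42),
      tau_self = 3.0,
      tau_other = 2.5,
      d_alpha_self_b2 = ifelse(.data$group == "OBS" & .data$subtype == "selfish",
                               -0.15, 0),
      d_alpha_other_b2 = ifelse(.data$group == "OBS" & .data$subtype == "selfish",
                                0.25, 0))
}

#' Specification of a synthetic cohort
#'
#' Collects everything [sample_cohort()] needs: group sizes, the proportion
#' of "selfish" subjects (those with `alpha_self > alpha_other` at
#' baseline), the effect table of cell means and block-2 shifts, population
#' SDs of the truncated-normal parameter distributions, the missing-response
#' rate, and the lognormal reaction-time model (self responses ~10% faster).
#'
#' @param n_obs,n_con Subjects in the observation / control groups
#'   (defaults 49 / 53).
#' @param p_selfish Probability that a subject is of the selfish subtype
#'   (default 0.64).
#' @param effects Effect table, see [default_effect_table()].
#' @param sd_alpha,sd_tau Population SDs of learning rates (default 0.15)
#'   and inverse temperatures (default 1.5).
#' @param missing_rate Per-trial probability of a missing response
#'   (default 0.01).
#' @param rt_meanlog_other Log-scale location of the "other" condition
#'   reaction times in ms (default `log(900)`); the "self" location is
#'   `rt_meanlog_other + log(0.9)`.
#' @param rt_sdlog Log-scale SD of reaction times (default 0.3).
#' @param seed Optional default seed used by [sample_cohort()].
#' @return A list of class `prlt_cohort_spec`.
#' @export
cohort_spec <- function(n_obs = 49, n_con = 53, p_selfish = 0.64,
                        effects = default_effect_table(),
                        sd_alpha = 0.15, sd_tau = 1.5,
                        missing_rate = 0.01,
                        rt_meanlog_other = log(900), rt_sdlog = 0.3,
                        seed = NULL) {
  stop_unless(is_count(n_obs) && n_obs >= 1 && is_count(n_con) && n_con >= 1,
              "group sizes must be positive integers")
  stop_unless(p_selfish >= 0 && p_selfish <= 1, "p_selfish must lie in [0, 1]")
  stop_unless(sd_alpha >= 0 && sd_tau >= 0, "population SDs must be non-negative")
  stop_unless(missing_rate >= 0 && missing_rate < 1,
              "missing_rate must lie in [0, 1)")
  need <- tidyr::expand_grid(group = c("OBS", "CON"),
                             subtype = c("selfish", "prosocial"))
  have <- dplyr::semi_join(need, effects, by = c("group", "subtype"))
  stop_unless(nrow(have) == nrow(need),
              "effects must contain every group x subtype cell")
  structure(list(n_obs = n_obs, n_con = n_con, p_selfish = p_selfish,
                 effects = effects, sd_alpha = sd_alpha, sd_tau = sd_tau,
                 missing_rate = missing_rate,
                 rt_meanlog_other = rt_meanlog_other, rt_sdlog = rt_sdlog,
                 seed = seed),
            class = "prlt_cohort_spec")
}

# Truncated-normal draw by rejection, with a safety fallback to clamping.
rtruncnorm1 <- function(mean, sd, lower, upper, max_tries = 200) {
  if (sd == 0) return(min(max(mean, lower), upper))
  for (i in seq_len(max_tries)) {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lower && x <= upper) return(x)
  }
  min(max(mean, lower), upper)
}

draw_block1_params <- function(cell, spec) {
  a_lo <- 0.01
  a_hi <- 0.99
  t_lo <- 0.1
  t_hi <- 15
  repeat {
    p <- c(alpha_self = rtruncnorm1(cell$alpha_self, spec$sd_alpha, a_lo, a_hi),
           alpha_other = rtruncnorm1(cell$alpha_other, spec$sd_alpha, a_lo, a_hi),
           tau_self = rtruncnorm1(cell$tau_self, spec$sd_tau, t_lo, t_hi),
           tau_other = rtruncnorm1(cell$tau_other, spec$sd_tau, t_lo, t_hi))
    pls <- p[["alpha_other"]] - p[["alpha_self"]]
    ok <- if (cell$subtype == "selfish") pls < 0 else pls >= 0
    if (ok) return(p)
  }
}

#' Generate a synthetic cohort of task datasets with known ground truth
#'
#' Samples each subject's subtype (selfish/prosocial), draws true per-block
#' separate-model parameters from truncated normals around the effect-table
#' cell means (block-1 draws are constrained so the sign of
#' `alpha_other - alpha_self` matches the subtype; block 2 adds the cell's
#' shifts; block 3 reuses block 1), simulates behavior with the delta-rule /
#' softmax agent on the task schedule, attaches lognormal reaction times
#' (self faster on average), and masks responses at the missingness rate.
#' Fully reproducible from the seed.
#'
#' @param spec A [cohort_spec()].
#' @param config Task structure, see [task_config()].
#' @param seed Integer seed (falls back to `spec$seed`).
#' @param v0 Initial arm value for the simulated agents.
#' @return A list of class `prlt_cohort` with elements `trials` (the trial
#'   table, schema of [read_trials()]) and `truth` (one row per subject x
#'   block of true parameters, plus `group` and `subtype`).
#' @export
sample_cohort <- function(spec = cohort_spec(), config = task_config(),
                          seed = NULL, v0 = 0.5) {
  stopifnot(inherits(spec, "prlt_cohort_spec"))
  seed <- if (is.null(seed)) spec$seed else seed
  if (!is.null(seed)) set.seed(seed)
  schedule <- build_schedule(config)
  n_total <- spec$n_obs + spec$n_con
  subjects <- tibble::tibble(
    subject_id = sprintf("S%03d", seq_len(n_total)),
    group = rep(c("OBS", "CON"), c(spec$n_obs, spec$n_con)),
    subtype = ifelse(stats::runif(n_total) < spec$p_selfish,
                     "selfish", "prosocial"))

  truth <- purrr::map_dfr(seq_len(n_total), function(i) {
    cell <- dplyr::filter(spec$effects, .data$group == subjects$group[i],
                          .data$subtype == subjects$subtype[i])
    b1 <- draw_block1_params(cell, spec)
    b2 <- b1
    b2[["alpha_self"]] <- min(max(b1[["alpha_self"]] + cell$d_alpha_self_b2, 0.01), 0.99)
    b2[["alpha_other"]] <- min(max(b1[["alpha_other"]] + cell$d_alpha_other_b2, 0.01), 0.99)
    per_block <- list(b1, b2, b1)[seq_len(config$n_blocks)]
    purrr::map_dfr(seq_along(per_block), function(b)
      tibble::tibble(subject_id = subjects$subject_id[i],
                     group = subjects$group[i], subtype = subjects$subtype[i],
                     block = b, !!!as.list(per_block[[b]])))
  })

  rt_meanlog <- c(self = spec$rt_meanlog_other + log(0.9),
                  other = spec$rt_meanlog_other)
  block_sched <- schedule[schedule$block == 1, ]
  trials <- purrr::map_dfr(seq_len(config$n_blocks), function(b) {
    tb <- dplyr::filter(truth, .data$block == b)
    purrr::map_dfr(c("self", "other"), function(cond) {
      sel <- which(block_sched$condition == cond)
      run <- sim_run(block_sched$high_arm[sel] == "a", config$p_high,
                     config$p_low, tb[[paste0("alpha_", cond)]],
                     tb[[paste0("tau_", cond)]], n_total, v0)
      n_tr <- length(sel)
      # matrices are agents x trials; lay out subject-major
      tibble::tibble(subject_id = rep(tb$subject_id, each = n_tr),
                     group = rep(tb$group, each = n_tr),
                     block = b,
                     trial = rep(block_sched$trial_in_block[sel], n_total),
                     condition = cond,
                     chosen = c("a", "b")[as.vector(t(run$choice))],
                     chose_high = as.integer(as.vector(t(run$hit))),
                     reward = as.integer(as.vector(t(run$reward))))
    })
  })
  trials$rt_ms <- round(stats::rlnorm(nrow(trials),
                                      rt_meanlog[trials$condition],
                                      spec$rt_sdlog), 1)
  miss <- stats::runif(nrow(trials)) < spec$missing_rate
  trials$chosen[miss] <- NA_character_
  trials$chose_high[miss] <- NA_integer_
  trials$reward[miss] <- NA_integer_
  trials$rt_ms[miss] <- NA_real_
  trials <- dplyr::arrange(trials, .data$subject_id, .data$block, .data$trial)
  structure(list(trials = trials, truth = truth, spec = spec, config = config),
            class = "prlt_cohort")
}

#' @export
print.prlt_cohort <- function(x, ...) {
  cat(sprintf("<prlt_cohort: %d subjects, %d trials, %d selfish / %d prosocial>\n",
              length(unique(x$truth$subject_id)), nrow(x$trials),
              sum(x$truth$subtype[!duplicated(x$truth$subject_id)] == "selfish"),
              sum(x$truth$subtype[!duplicated(x$truth$subject_id)] == "prosocial")))
  invisible(x)
}

#' Parameter and subtype recovery report
#'
#' Compares fitted separate-model parameters against the generating truth:
#' Pearson correlation and mean bias (fit minus truth) per parameter per
#' block, and the fraction of subjects whose fitted block-1 PLS sign
#' (`alpha_other - alpha_self`) agrees with the true subtype. When either
#' the true or the fitted values of a parameter are (near-)constant the
#' correlation is undefined and the report flags the comparison degenerate.
#'
#' @param truth Truth table from [sample_cohort()].
#' @param fits M2 fit rows covering every subject x block in `truth`.
#' @return A list of class `prlt_recovery`: `params` (per parameter x block
#'   `r`, `bias`, `degenerate`), `subtype_agreement`, `n_subjects`.
#' @export
truth_recovery_report <- function(truth, fits) {
  fits <- dplyr::filter(fits, .data$model == "M2")
  fits <- fits[, c("subject_id", "block", "alpha_self", "alpha_other",
                   "tau_self", "tau_other")]
  joined <- dplyr::inner_join(
    truth, fits, by = c("subject_id", "block"), suffix = c("_true", "_fit"))
  stop_unless(nrow(joined) == nrow(truth),
              "fits must cover every subject x block in the truth table")
  pars <- c("alpha_self", "alpha_other", "tau_self", "tau_other")
  params <- purrr::map_dfr(pars, function(p) {
    joined |>
      dplyr::group_by(.data$block) |>
      dplyr::summarise(
        parameter = p,
        sd_true = stats::sd(.data[[paste0(p, "_true")]]),
        sd_fit = stats::sd(.data[[paste0(p, "_fit")]]),
        r_raw = suppressWarnings(
          stats::cor(.data[[paste0(p, "_true")]], .data[[paste0(p, "_fit")]])),
        bias = mean(.data[[paste0(p, "_fit")]] - .data[[paste0(p, "_true")]]),
        .groups = "drop") |>
      dplyr::mutate(degenerate = .data$sd_true < 1e-8 | .data$sd_fit < 1e-8,
                    r = ifelse(.data$degenerate, NA_real_, .data$r_raw))
  })
  b1 <- dplyr::filter(joined, .data$block == 1)
  fitted_selfish <- (b1$alpha_other_fit - b1$alpha_self_fit) < 0
  agreement <- mean(fitted_selfish == (b1$subtype == "selfish"))
  structure(list(params = params[, c("parameter", "block", "r", "bias", "degenerate")],
                 subtype_agreement = agreement,
                 n_subjects = nrow(b1)),
            class = "prlt_recovery")
}

#' @export
print.prlt_recovery <- function(x, ...) {
  cat(sprintf("<prlt_recovery: %d subjects, subtype agreement %.3f>\n",
              x$n_subjects, x$subtype_agreement))
  print(x$params)
  invisible(x)
}
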