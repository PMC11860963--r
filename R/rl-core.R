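#' Softmax choice probability
#'
#' Probability of choosing arm "a" given the two value estimates, under the
#' logistic softmax \eqn{P(a) = 1 / (1 + e^{-\tau (V_a - V_b)})}. The inverse
#' temperature \eqn{\tau} scales sensitivity to the value difference:
#' \eqn{\tau = 0} gives indifference (0.5), large \eqn{\tau} approaches greedy
#' choice. Computed through `plogis()`, which is shift-invariant and never
#' overflows; the log-probability path used by [sequence_nll()] stays finite
#' for \eqn{|\tau (V_a - V_b)|} up to 1e4 and beyond.
#'
#' @param v_a,v_b Value estimates of arms a and b (vectorized).
#' @param tau Inverse temperature, `tau >= 0`.
#' @return `P(choose a)`, same length as the inputs.
#' @examples
#' choice_prob(1, 0, tau = 1)  # 0.7310586
#' @export
choice_prob <- function(v_a, v_b, tau) {
  stop_unless(all(is.finite(v_a)) && all(is.finite(v_b)), "values must be finite")
  stop_unless(all(is.finite(tau)) && all(tau >= 0), "tau must be non-negative")
  stats::plogis(tau * (v_a - v_b))
}

#' Delta-rule value update
#'
#' Moves the chosen arm's value toward the observed reward by the learning
#' rate: \eqn{V \leftarrow V + \alpha (R - V)}. The unchosen arm is left
#' untouched.
#'
#' @param v_a,v_b Current value estimates.
#' @param chosen `"a"` or `"b"`.
#' @param reward Observed outcome, 0 or 1.
#' @param alpha Learning rate in `[0, 1]`.
#' @return A list with updated `v_a` and `v_b`.
#' @examples
#' update_values(0.5, 0.5, "a", reward = 1, alpha = 0.2)  # v_a = 0.6
#' @export
update_values <- function(v_a, v_b, chosen, reward, alpha) {
  stop_unless(all(alpha >= 0 & alpha <= 1), "alpha must lie in [0, 1]")
  stop_unless(all(chosen %in% c("a", "b")), "chosen must be \"a\" or \"b\"")
  stop_unless(all(reward %in% c(0, 1)), "reward must be 0 or 1")
  is_a <- chosen == "a"
  list(v_a = ifelse(is_a, v_a + alpha * (reward - v_a), v_a),
       v_b = ifelse(is_a, v_b, v_b + alpha * (reward - v_b)))
}

#' Parameter sets for the candidate models
#'
#' `params_shared()` holds one learning rate and one inverse temperature used
#' for both reward conditions (model M1); `params_separate()` holds a pair per
#' condition (model M2). The null model M0 has no parameters (choice
#' probability fixed at 0.5).
#'
#' @param alpha,alpha_self,alpha_other Learning rates in `[0, 1]`.
#' @param tau,tau_self,tau_other Inverse temperatures, `>= 0`.
#' @return A named list of class `prlt_params`.
#' @export
params_shared <- function(alpha, tau) {
  stop_unless(is.numeric(alpha) && alpha >= 0 && alpha <= 1, "alpha must lie in [0, 1]")
  stop_unless(is.numeric(tau) && tau >= 0, "tau must be non-negative")
  structure(list(alpha = alpha, tau = tau), model = "M1", class = "prlt_params")
}

#' @rdname params_shared
#' @export
params_separate <- function(alpha_self, alpha_other, tau_self, tau_other) {
  for (a in c(alpha_self, alpha_other))
    stop_unless(is.numeric(a) && a >= 0 && a <= 1, "learning rates must lie in [0, 1]")
  for (t in c(tau_self, tau_other))
    stop_unless(is.numeric(t) && t >= 0, "inverse temperatures must be non-negative")
  structure(list(alpha_self = alpha_self, alpha_other = alpha_other,
                 tau_self = tau_self, tau_other = tau_other),
            model = "M2", class = "prlt_params")
}

# Negative log-likelihood of one condition's choice run. ch is integer 1 (arm
# a) / 2 (arm b) with NA for missing responses; missing trials contribute
# nothing and trigger no update. The log-probability uses the stable branch
# log P = min(d, 0) - log1p(exp(-|d|)), finite for |tau * dV| up to ~1e4 and
# beyond; written as straight arithmetic because this loop dominates fitting
# time.
nll_run <- function(ch, rew, alpha, tau, v0) {
  keep <- !is.na(ch)
  if (!all(keep)) {
    ch <- ch[keep]
    rew <- rew[keep]
  }
  va <- v0
  vb <- v0
  nll <- 0
  for (i in seq_along(ch)) {
    d <- tau * (va - vb)
    if (ch[i] == 1L) {
      nll <- nll - (if (d < 0) d - log1p(exp(d)) else -log1p(exp(-d)))
      va <- va + alpha * (rew[i] - va)
    } else {
      nll <- nll - (if (d > 0) -d - log1p(exp(-d)) else -log1p(exp(d)))
      vb <- vb + alpha * (rew[i] - vb)
    }
  }
  nll
}

# Normalize a records data frame to integer choices + rewards per condition.
split_runs <- function(records) {
  ch <- match(records[["chosen"]], c("a", "b"))
  rew <- records[["reward"]]
  if (!is.null(records[["condition"]])) {
    idx <- split(seq_along(ch), records[["condition"]])
  } else {
    idx <- list(self = seq_along(ch))
  }
  lapply(idx, function(i) list(ch = ch[i], rew = rew[i]))
}

#' Sequence negative log-likelihood
#'
#' Negative log-likelihood of an observed choice sequence under one of the
#' three candidate models: M0 (every choice has probability 0.5), M1 (shared
#' `alpha`/`tau` across conditions) or M2 (separate `alpha`/`tau` per
#' condition). Each condition carries its own value pair, initialized at
#' `v0`; values are updated trial by trial with the delta rule and choice
#' probabilities come from the softmax. Missing responses (`chosen` = `NA`)
#' are skipped entirely: no likelihood contribution, no value update.
#'
#' @param records Data frame in presentation order with columns `chosen`
#'   (`"a"`/`"b"`/`NA`), `reward` (0/1/`NA`) and, for M1/M2, `condition`
#'   (`"self"`/`"other"`). Without a `condition` column all trials are
#'   treated as one bandit.
#' @param params A [params_shared()] (M1) or [params_separate()] (M2) set;
#'   ignored for M0.
#' @param model `"M0"`, `"M1"` or `"M2"`.
#' @param v0 Initial value of both arms (default 0.5, the midpoint of the
#'   0/1 reward scale).
#' @return The negative log-likelihood (a non-negative scalar).
#' @export
sequence_nll <- function(records, params = NULL, model = c("M2", "M1", "M0"),
                         v0 = 0.5) {
  model <- match.arg(model)
  n_obs <- sum(!is.na(records$chosen))
  stop_unless(n_obs >= 1, "no non-missing trials: likelihood undefined")
  if (model == "M0") return(n_obs * log(2))
  runs <- split_runs(records)
  if (model == "M1") {
    stop_unless(!is.null(params$alpha), "M1 requires params_shared()")
    return(sum(vapply(runs, function(r)
      nll_run(r$ch, r$rew, params$alpha, params$tau, v0), numeric(1))))
  }
  stop_unless(!is.null(params$alpha_self), "M2 requires params_separate()")
  stop_unless(all(names(runs) %in% c("self", "other")),
              "M2 requires conditions named self/other")
  sum(vapply(names(runs), function(cond) {
    r <- runs[[cond]]
    nll_run(r$ch, r$rew,
            params[[paste0("alpha_", cond)]], params[[paste0("tau_", cond)]], v0)
  }, numeric(1)))
}

# Vectorized simulation engine: one block-condition run for n agents in
# parallel. alpha/tau are scalars or length-n vectors. Returns matrices
# (n x n_trials) of choices (1/2), rewards and high-arm hits.
sim_run <- function(high_is_a, p_high, p_low, alpha, tau, n_agents, v0) {
  n_trials <- length(high_is_a)
  va <- rep(v0, n_agents)
  vb <- rep(v0, n_agents)
  ch <- matrix(0L, n_agents, n_trials)
  rw <- matrix(0L, n_agents, n_trials)
  hit <- matrix(FALSE, n_agents, n_trials)
  for (t in seq_len(n_trials)) {
    p_a <- stats::plogis(tau * (va - vb))
    choose_a <- stats::runif(n_agents) < p_a
    correct <- choose_a == high_is_a[t]
    rew <- as.integer(stats::runif(n_agents) < ifelse(correct, p_high, p_low))
    ch[, t] <- ifelse(choose_a, 1L, 2L)
    rw[, t] <- rew
    hit[, t] <- correct
    va <- ifelse(choose_a, va + alpha * (rew - va), va)
    vb <- ifelse(choose_a, vb, vb + alpha * (rew - vb))
  }
  list(choice = ch, reward = rw, hit = hit)
}

resolve_sim_params <- function(params, model) {
  if (model == "M0") {
    list(self = c(0, 0), other = c(0, 0))
  } else if (model == "M1") {
    stop_unless(!is.null(params$alpha), "M1 requires params_shared()")
    list(self = c(params$alpha, params$tau), other = c(params$alpha, params$tau))
  } else {
    stop_unless(!is.null(params$alpha_self), "M2 requires params_separate()")
    list(self = c(params$alpha_self, params$tau_self),
         other = c(params$alpha_other, params$tau_other))
  }
}

#' Simulate an agent on a schedule
#'
#' Plays a softmax/delta-rule learner through a [build_schedule()] schedule:
#' choices are sampled from [choice_prob()], the chosen arm's reward from its
#' current reward probability, and values updated with [update_values()].
#' Value pairs are reset to `v0` at every block boundary (blocks are fitted
#' independently downstream).
#'
#' @param schedule A `prlt_schedule`.
#' @param params Parameter set matching `model` (`NULL` for M0).
#' @param model `"M2"`, `"M1"` or `"M0"`.
#' @param seed Optional integer seed for reproducibility.
#' @param v0 Initial arm value (default 0.5).
#' @return A tibble with one row per trial (`block`, `trial_in_block` aliased
#'   as `trial`, `condition`, `chosen`, `chose_high`, `reward`) and an `"hrp"`
#'   attribute: the proportion of trials on which the currently high arm was
#'   chosen, per condition.
#' @export
simulate_agent <- function(schedule, params = NULL, model = c("M2", "M1", "M0"),
                           seed = NULL, v0 = 0.5) {
  model <- match.arg(model)
  stopifnot(inherits(schedule, "prlt_schedule"))
  if (!is.null(seed)) set.seed(seed)
  cfg <- attr(schedule, "config")
  pp <- resolve_sim_params(params, model)
  out <- schedule[, c("block", "trial_in_block", "condition")]
  out$chosen <- NA_character_
  out$chose_high <- NA_integer_
  out$reward <- NA_integer_
  for (b in unique(schedule$block)) {
    for (cond in c("self", "other")) {
      sel <- which(schedule$block == b & schedule$condition == cond)
      if (!length(sel)) next
      run <- sim_run(schedule$high_arm[sel] == "a", cfg$p_high, cfg$p_low,
                     pp[[cond]][1], pp[[cond]][2], 1L, v0)
      out$chosen[sel] <- c("a", "b")[run$choice[1, ]]
      out$chose_high[sel] <- as.integer(run$hit[1, ])
      out$reward[sel] <- run$reward[1, ]
    }
  }
  out <- dplyr::rename(out, trial = "trial_in_block")
  attr(out, "hrp") <- vapply(split(out$chose_high, out$condition), mean, numeric(1))
  out
}

#' Proportion of high-probability-arm choices
#'
#' The behavioral summary the models are checked against: per condition (and
#' optionally per block), the proportion of non-missing trials on which the
#' arm currently carrying the high reward probability was chosen.
#'
#' @param records Data frame with `condition`, `chose_high` and optionally
#'   `block` columns.
#' @param by_block If `TRUE`, compute per block as well.
#' @return A tibble with columns `condition` (and `block`) and `hrp`.
#' @export
hrp_summary <- function(records, by_block = FALSE) {
  grp <- if (by_block) c("block", "condition") else "condition"
  records |>
    dplyr::filter(!is.na(.data$chose_high)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(hrp = mean(.data$chose_high), .groups = "drop")
}
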