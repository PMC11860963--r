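# Shared fixtures, built once per test run. Sizes are kept moderate so the
# whole suite stays fast; seeds are fixed for reproducibility.

fx_env <- new.env(parent = emptyenv())

fx_memo <- function(name, expr) {
  if (is.null(fx_env[[name]])) fx_env[[name]] <- force(expr)
  fx_env[[name]]
}

# A mid-sized cohort with the default effect structure (planted block-2
# shifts in OBS-selfish) and its separate-parameter fits.
fx_cohort <- function() fx_memo("cohort",
  sample_cohort(cohort_spec(n_obs = 20, n_con = 20), task_config(), seed = 424242))

fx_fits_m2 <- function() fx_memo("fits_m2", fit_cohort(fx_cohort()$trials, models = "M2"))

fx_schedule <- function() fx_memo("schedule", build_schedule(task_config()))

# Straight-line reference NLL, independent of the package internals: walks
# the trial list once, accumulating -log P with explicit arithmetic.
ref_nll <- function(choices, rewards, alpha, tau, v0 = 0.5) {
  va <- v0; vb <- v0; nll <- 0
  for (i in seq_along(choices)) {
    if (is.na(choices[i])) next
    p_a <- 1 / (1 + exp(-tau * (va - vb)))
    if (choices[i] == "a") {
      nll <- nll - log(p_a)
      va <- va + alpha * (rewards[i] - va)
    } else {
      nll <- nll - log(1 - p_a)
      vb <- vb + alpha * (rewards[i] - vb)
    }
  }
  nll
}

# Random single-condition record tables for property tests.
random_records <- function(n, seed, p_missing = 0) {
  set.seed(seed)
  chosen <- sample(c("a", "b"), n, replace = TRUE)
  miss <- runif(n) < p_missing
  chosen[miss] <- NA
  tibble::tibble(
    condition = "self",
    chosen = chosen,
    reward = ifelse(is.na(chosen), NA_integer_, rbinom(n, 1, 0.5)))
}
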