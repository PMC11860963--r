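#' Posterior predictive check of separate-parameter fits
#'
#' For each subject x block M2 fit, simulates `n_sims` agents with the
#' fitted parameters on the block's schedule, averages the proportion of
#' high-probability-arm choices (HRP) per condition, and pairs it with the
#' observed HRP. High actual-predicted agreement indicates the fitted
#' parameters capture the behavior they were estimated from.
#'
#' @param fits M2 fit rows from [fit_cohort()] (`model == "M2"` only).
#' @param trials The trial table the fits came from (for the actual HRP).
#' @param schedule The block schedule the subjects played; only its
#'   single-block structure is used.
#' @param n_sims Simulated agents per subject x block (default 1000).
#' @param seed Optional integer seed.
#' @param v0 Initial arm value (default 0.5).
#' @return A tibble of class `prlt_ppc`: `subject_id`, `block`, `condition`,
#'   `predicted_hrp`, `actual_hrp`, `n_sims`. `glance()` gives the
#'   actual-predicted Pearson correlation.
#' @export
posterior_predictive <- function(fits, trials, schedule, n_sims = 1000,
                                 seed = NULL, v0 = 0.5) {
  stop_unless(n_sims >= 1, "n_sims must be at least 1")
  fits <- dplyr::filter(fits, .data$model == "M2")
  stop_unless(nrow(fits) > 0, "posterior predictive checks require M2 fits")
  if (!is.null(seed)) set.seed(seed)
  cfg <- attr(schedule, "config")
  block1 <- schedule[schedule$block == schedule$block[1], ]
  actual <- trials |>
    dplyr::filter(!is.na(.data$chose_high)) |>
    dplyr::group_by(.data$subject_id, .data$block, .data$condition) |>
    dplyr::summarise(actual_hrp = mean(.data$chose_high), .groups = "drop")
  pred <- purrr::map_dfr(seq_len(nrow(fits)), function(i) {
    f <- fits[i, ]
    purrr::map_dfr(c("self", "other"), function(cond) {
      sel <- block1$condition == cond
      run <- sim_run(block1$high_arm[sel] == "a", cfg$p_high, cfg$p_low,
                     f[[paste0("alpha_", cond)]], f[[paste0("tau_", cond)]],
                     n_sims, v0)
      tibble::tibble(subject_id = f$subject_id, block = f$block,
                     condition = cond, predicted_hrp = mean(run$hit),
                     n_sims = n_sims)
    })
  })
  out <- dplyr::inner_join(pred, actual,
                           by = c("subject_id", "block", "condition"))
  out <- out[, c("subject_id", "block", "condition",
                 "predicted_hrp", "actual_hrp", "n_sims")]
  class(out) <- c("prlt_ppc", class(out))
  out
}

#' @exportS3Method generics::glance
glance.prlt_ppc <- function(x, ...) {
  tibble::tibble(
    r = stats::cor(x$actual_hrp, x$predicted_hrp),
    n = nrow(x),
    n_sims = x$n_sims[1])
}

#' Learning-rate / inverse-temperature grid simulation
#'
#' Simulates the separate-parameter model on the task schedule for every
#' combination of `alpha_grid` x `tau_grid` (the same pair driving both
#' conditions), records each cell's mean HRP over `n_sims` agents, and
#' correlates cell `alpha` and cell `tau` with cell mean HRP across all
#' cells. The comparison of the two correlations shows which parameter
#' drives overall choice accuracy under reversals.
#'
#' @param schedule Task schedule (defaults to one [task_config()] block;
#'   only the first block of a multi-block schedule is simulated since
#'   values reset at block boundaries).
#' @param alpha_grid,tau_grid Grid margins (defaults `alpha` 0.1..1.0 step
#'   0.1, `tau` 0.5..10 step 0.5; 200 cells). A margin collapsed to a single
#'   value leaves that margin's correlation `NA` (with a warning); a
#'   single-cell grid is rejected.
#' @param n_sims Simulated agents per cell (default 1000).
#' @param seed Optional integer seed.
#' @param v0 Initial arm value (default 0.5).
#' @return A tibble of class `prlt_grid` (`alpha`, `tau`, `mean_hrp`,
#'   `n_sims`) with attributes `r_alpha` and `r_tau`; see `glance()`.
#' @export
grid_predictiveness <- function(schedule = build_schedule(task_config(n_blocks = 1)),
                                alpha_grid = seq(0.1, 1, by = 0.1),
                                tau_grid = seq(0.5, 10, by = 0.5),
                                n_sims = 1000, seed = NULL, v0 = 0.5) {
  stop_unless(length(alpha_grid) >= 1 && length(tau_grid) >= 1,
              "grids must be non-empty")
  stop_unless(length(alpha_grid) * length(tau_grid) >= 2,
              "a single-cell grid leaves both correlations undefined")
  stop_unless(n_sims >= 1, "n_sims must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  cfg <- attr(schedule, "config")
  block1 <- schedule[schedule$block == schedule$block[1], ]
  runs_by_cond <- lapply(c("self", "other"), function(cond)
    block1$high_arm[block1$condition == cond] == "a")
  runs_by_cond <- runs_by_cond[lengths(runs_by_cond) > 0]
  cells <- tidyr::expand_grid(alpha = alpha_grid, tau = tau_grid)
  cells$mean_hrp <- purrr::map2_dbl(cells$alpha, cells$tau, function(a, t) {
    hits <- lapply(runs_by_cond, function(high_is_a)
      sim_run(high_is_a, cfg$p_high, cfg$p_low, a, t, n_sims, v0)$hit)
    mean(rowMeans(do.call(cbind, hits)))
  })
  cells$n_sims <- n_sims
  r_alpha <- if (length(alpha_grid) > 1) {
    stats::cor(cells$alpha, cells$mean_hrp)
  } else {
    warning("alpha grid collapsed to a single value; r_alpha undefined")
    NA_real_
  }
  r_tau <- if (length(tau_grid) > 1) {
    stats::cor(cells$tau, cells$mean_hrp)
  } else {
    warning("tau grid collapsed to a single value; r_tau undefined")
    NA_real_
  }
  structure(cells, r_alpha = r_alpha, r_tau = r_tau,
            class = c("prlt_grid", class(cells)))
}

#' @exportS3Method generics::glance
glance.prlt_grid <- function(x, ...) {
  tibble::tibble(r_alpha = attr(x, "r_alpha"), r_tau = attr(x, "r_tau"),
                 n_cells = nrow(x), n_sims = x$n_sims[1])
}

#' @export
print.prlt_grid <- function(x, ...) {
  cat(sprintf("<prlt_grid: %d cells, %d sims/cell, r_alpha = %.3f, r_tau = %.3f>\n",
              nrow(x), x$n_sims[1], attr(x, "r_alpha"), attr(x, "r_tau")))
  NextMethod()
}
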