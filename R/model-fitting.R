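#' Bayesian information criterion
#'
#' `bic = k * log(n) + 2 * nll`, where `n` is the number of non-missing
#' trials entering the likelihood. Lower is better.
#'
#' @param nll Negative log-likelihood.
#' @param k Number of free parameters.
#' @param n Number of observations (`>= 1`).
#' @return The BIC score.
#' @export
bic <- function(nll, k, n) {
  stop_unless(all(n >= 1), "n must be at least 1")
  k * log(n) + 2 * nll
}

default_fit_settings <- function(tau_max = 20, v0 = 0.5,
                                 alpha_starts = seq(0.1, 0.9, by = 0.1),
                                 tau_starts = c(0.5, 1, 3, 5, 10),
                                 n_refine = 3) {
  list(tau_max = tau_max, v0 = v0, alpha_starts = alpha_starts,
       tau_starts = tau_starts, n_refine = n_refine)
}

# Fit (alpha, tau) for a single condition run by multi-start bounded MLE:
# evaluate the NLL on the fixed start grid, then refine the n_refine best
# starts with L-BFGS-B. Fully deterministic.
fit_run <- function(ch, rew, st) {
  obj <- function(p) nll_run(ch, rew, p[1], p[2], st$v0)
  starts <- expand.grid(alpha = st$alpha_starts, tau = st$tau_starts)
  g <- vapply(seq_len(nrow(starts)), function(i)
    obj(c(starts$alpha[i], starts$tau[i])), numeric(1))
  top <- order(g)[seq_len(min(st$n_refine, nrow(starts)))]
  best <- NULL
  for (i in top) {
    fit <- tryCatch(
      stats::optim(c(starts$alpha[i], starts$tau[i]), obj, method = "L-BFGS-B",
                   lower = c(0, 0), upper = c(1, st$tau_max),
                   control = list(factr = 1e9)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    i <- top[1]
    best <- list(par = c(starts$alpha[i], starts$tau[i]), value = g[i],
                 convergence = 1L)
  }
  list(alpha = best$par[1], tau = best$par[2], nll = best$value,
       converged = best$convergence == 0L, n_starts = nrow(starts))
}

#' Fit one model to one subject-block of choices
#'
#' Maximum-likelihood estimation over the bounded box `alpha` in `[0, 1]`,
#' `tau` in `[0, tau_max]`, using the best of a fixed start grid (`alpha` in
#' 0.1..0.9, `tau` in \{0.5, 1, 3, 5, 10\}) refined by L-BFGS-B. For M2 the
#' two conditions decouple and are fitted independently; for M1 one
#' `(alpha, tau)` pair is optimized over both conditions jointly; M0 has a
#' closed form. Refitting the same records reproduces the result bit for bit.
#'
#' Data in which a condition run has fewer than two non-missing trials or a
#' single repeated choice are flagged `converged = FALSE` rather than
#' raising an error.
#'
#' @param records Trial rows in presentation order (columns `condition`,
#'   `chosen`, `reward`; `subject_id`/`block` are carried through if present
#'   and unique).
#' @param model `"M0"`, `"M1"` or `"M2"`.
#' @param tau_max Upper fitting bound for `tau` (default 20; beyond this the
#'   softmax is effectively greedy).
#' @param v0 Initial arm value (default 0.5).
#' @param n_refine Number of grid starts refined by the local optimizer.
#' @return A one-row tibble: `model`, parameter columns (`NA` where a
#'   parameter does not belong to the model), `nll`, `n_trials`, `k`, `bic`,
#'   `n_starts`, `converged`.
#' @export
fit_subject_block <- function(records, model = c("M2", "M1", "M0"),
                              tau_max = 20, v0 = 0.5, n_refine = 3) {
  model <- match.arg(model)
  st <- default_fit_settings(tau_max = tau_max, v0 = v0, n_refine = n_refine)
  runs <- split_runs(records)
  n_obs <- sum(!is.na(records$chosen))
  stop_unless(n_obs >= 1, "no non-missing trials to fit")
  degenerate <- any(vapply(runs, function(r) {
    ch <- r$ch[!is.na(r$ch)]
    length(ch) < 2 || length(unique(ch)) < 2
  }, logical(1)))

  row <- tibble::tibble(model = model, alpha = NA_real_, tau = NA_real_,
                        alpha_self = NA_real_, alpha_other = NA_real_,
                        tau_self = NA_real_, tau_other = NA_real_)
  if (model == "M0") {
    nll <- n_obs * log(2)
    k <- 0L
    row$n_starts <- 0L
    row$converged <- TRUE
  } else if (model == "M1") {
    obj <- function(p) sum(vapply(runs, function(r)
      nll_run(r$ch, r$rew, p[1], p[2], st$v0), numeric(1)))
    starts <- expand.grid(alpha = st$alpha_starts, tau = st$tau_starts)
    g <- vapply(seq_len(nrow(starts)), function(i)
      obj(c(starts$alpha[i], starts$tau[i])), numeric(1))
    top <- order(g)[seq_len(min(st$n_refine, nrow(starts)))]
    best <- NULL
    for (i in top) {
      fit <- tryCatch(
        stats::optim(c(starts$alpha[i], starts$tau[i]), obj, method = "L-BFGS-B",
                     lower = c(0, 0), upper = c(1, st$tau_max),
                     control = list(factr = 1e9)),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
    }
    row$alpha <- best$par[1]
    row$tau <- best$par[2]
    nll <- best$value
    k <- 2L
    row$n_starts <- nrow(starts)
    row$converged <- best$convergence == 0L && !degenerate
  } else {
    stop_unless(all(names(runs) %in% c("self", "other")),
                "M2 requires conditions named self/other")
    fits <- lapply(runs, function(r) fit_run(r$ch, r$rew, st))
    for (cond in names(fits)) {
      row[[paste0("alpha_", cond)]] <- fits[[cond]]$alpha
      row[[paste0("tau_", cond)]] <- fits[[cond]]$tau
    }
    nll <- sum(vapply(fits, function(f) f$nll, numeric(1)))
    k <- 2L * length(fits)
    row$n_starts <- fits[[1]]$n_starts
    row$converged <- all(vapply(fits, function(f) f$converged, logical(1))) &&
      !degenerate
  }
  row$nll <- nll
  row$n_trials <- n_obs
  row$k <- k
  row$bic <- bic(nll, k, n_obs)
  for (col in c("subject_id", "block", "group")) {
    if (col %in% names(records) && length(unique(records[[col]])) == 1)
      row[[col]] <- records[[col]][1]
  }
  dplyr::relocate(row, dplyr::any_of(c("subject_id", "group", "block")))
}

#' Fit models to every subject and block of a cohort
#'
#' Applies [fit_subject_block()] to each `subject_id` x `block` cell of a
#' trial table, for each requested model.
#'
#' @param trials A trial table (see [read_trials()] for the schema).
#' @param models Character vector from `c("M0", "M1", "M2")`.
#' @inheritParams fit_subject_block
#' @return A tibble of fit rows, one per subject x block x model.
#' @export
fit_cohort <- function(trials, models = c("M0", "M1", "M2"),
                       tau_max = 20, v0 = 0.5, n_refine = 3) {
  stop_unless(all(models %in% c("M0", "M1", "M2")), "unknown model label")
  cells <- dplyr::group_split(dplyr::group_by(trials, .data$subject_id, .data$block))
  purrr::map_dfr(cells, function(cell) {
    purrr::map_dfr(models, function(m)
      fit_subject_block(cell, model = m, tau_max = tau_max, v0 = v0,
                        n_refine = n_refine))
  })
}

#' Cohort-level model comparison by summed BIC
#'
#' Sums BIC across subjects within each block for each model and reports
#' the differences relative to the block's winning (lowest summed BIC)
#' model, the standard fixed-effects aggregation.
#'
#' @param fits Fit rows from [fit_cohort()].
#' @param models Models to compare (default all present).
#' @return A tibble with one row per block x model: `sum_bic`, `n_subjects`,
#'   `winner` and `delta_bic` (model minus winner; 0 for the winner).
#' @export
compare_models <- function(fits, models = NULL) {
  if (is.null(models)) models <- unique(fits$model)
  fits <- dplyr::filter(fits, .data$model %in% models)
  cover <- fits |>
    dplyr::count(.data$block, .data$subject_id) |>
    dplyr::filter(.data$n != length(models))
  if (nrow(cover) > 0) {
    stop("subjects missing fits for some models: ",
         paste(unique(cover$subject_id), collapse = ", "), call. = FALSE)
  }
  fits |>
    dplyr::group_by(.data$block, .data$model) |>
    dplyr::summarise(sum_bic = sum(.data$bic),
                     n_subjects = dplyr::n(), .groups = "drop_last") |>
    dplyr::mutate(winner = .data$model[which.min(.data$sum_bic)],
                  delta_bic = .data$sum_bic - min(.data$sum_bic)) |>
    dplyr::ungroup()
}

#' Apply the cohort exclusion rules
#'
#' A subject is excluded when (a) any block has more than `max_missing_frac`
#' of its responses missing, or (b) the separate-parameter fit of block 1
#' estimates the "self" learning rate at zero (within `alpha_tol` of the
#' boundary), i.e. no evidence of learning even for the subject's own
#' reward. Reasons are recorded per subject.
#'
#' @param trials Trial table for the cohort.
#' @param fits Fit rows including block-1 M2 fits for every subject.
#' @param alpha_tol Boundary tolerance for "estimated to be zero"
#'   (default 1e-6).
#' @param max_missing_frac Largest tolerated per-block missingness
#'   (default 0.5).
#' @return A tibble with `subject_id`, `included` and `reasons`
#'   (empty string when included).
#' @export
apply_exclusions <- function(trials, fits, alpha_tol = 1e-6,
                             max_missing_frac = 0.5) {
  m2b1 <- dplyr::filter(fits, .data$model == "M2", .data$block == 1)
  stop_unless(all(unique(trials$subject_id) %in% m2b1$subject_id),
              "block-1 M2 fits required for every subject")
  missing_tbl <- trials |>
    dplyr::group_by(.data$subject_id, .data$block) |>
    dplyr::summarise(frac_missing = mean(is.na(.data$chosen)), .groups = "drop") |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(too_missing = any(.data$frac_missing > max_missing_frac))
  out <- missing_tbl |>
    dplyr::left_join(m2b1[, c("subject_id", "alpha_self")], by = "subject_id") |>
    dplyr::mutate(
      no_self_learning = .data$alpha_self <= alpha_tol,
      included = !.data$too_missing & !.data$no_self_learning,
      reasons = purrr::map2_chr(.data$too_missing, .data$no_self_learning,
        function(m, z) paste(c(if (m) "missing", if (z) "no self-learning"),
                             collapse = ";")))
  out[, c("subject_id", "included", "reasons")]
}
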