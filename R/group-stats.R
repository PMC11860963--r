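#' Subject-level behavioral and parameter summaries
#'
#' Builds the per-subject analysis table: per block and condition the HRP,
#' the mean z-scored reaction time, and the fitted separate-model
#' parameters; per block the prosocial learning sensitivity
#' `PLS = alpha_other - alpha_self`; and the subject's label, `"Selfish"`
#' when block-1 PLS is negative and `"Prosocial"` when it is zero or
#' positive. Reaction times are z-scored within subject within block across
#' all non-missing trials, then averaged per condition; a block with zero RT
#' variance yields z-scores of 0 and is flagged.
#'
#' @param trials Trial table for the cohort.
#' @param fits Fit rows containing an M2 fit for every subject x block.
#' @param inclusion Optional exclusion table from [apply_exclusions()]; when
#'   supplied, an `included` flag is attached (all rows are kept).
#' @return A tibble with one row per subject x block: `subject_id`, `group`,
#'   `block`, `hrp_self`, `hrp_other`, `zrt_self`, `zrt_other`,
#'   `alpha_self`, `alpha_other`, `tau_self`, `tau_other`, `pls`, `label`,
#'   `zrt_degenerate`, and `included`.
#' @export
summarize_subjects <- function(trials, fits, inclusion = NULL) {
  m2 <- dplyr::filter(fits, .data$model == "M2")
  n_blocks <- length(unique(trials$block))
  cover <- m2 |> dplyr::count(.data$subject_id)
  bad <- cover$subject_id[cover$n < n_blocks]
  missing_subj <- setdiff(unique(trials$subject_id), cover$subject_id)
  stop_unless(length(bad) == 0 && length(missing_subj) == 0,
              paste("M2 fits missing for subjects:",
                    paste(c(bad, missing_subj), collapse = ", ")))

  behav <- trials |>
    dplyr::group_by(.data$subject_id, .data$block) |>
    dplyr::mutate(zrt = {
      rt <- .data$rt_ms
      s <- stats::sd(rt, na.rm = TRUE)
      m <- mean(rt, na.rm = TRUE)
      if (is.na(s) || s == 0) ifelse(is.na(rt), NA_real_, 0) else (rt - m) / s
    },
    zrt_degenerate = {
      s <- stats::sd(.data$rt_ms, na.rm = TRUE)
      is.na(s) || s == 0
    }) |>
    dplyr::group_by(.data$subject_id, .data$group, .data$block,
                    .data$condition, .data$zrt_degenerate) |>
    dplyr::summarise(hrp = mean(.data$chose_high[!is.na(.data$chose_high)]),
                     zrt = mean(.data$zrt, na.rm = TRUE), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "condition", values_from = c("hrp", "zrt"))

  out <- behav |>
    dplyr::inner_join(
      m2[, c("subject_id", "block", "alpha_self", "alpha_other",
             "tau_self", "tau_other")],
      by = c("subject_id", "block")) |>
    dplyr::mutate(pls = .data$alpha_other - .data$alpha_self)
  labels <- out |>
    dplyr::filter(.data$block == 1) |>
    dplyr::mutate(label = ifelse(.data$pls < 0, "Selfish", "Prosocial")) |>
    dplyr::select("subject_id", "label")
  out <- dplyr::left_join(out, labels, by = "subject_id")
  if (!is.null(inclusion)) {
    out <- dplyr::left_join(out, inclusion[, c("subject_id", "included")],
                            by = "subject_id")
  } else {
    out$included <- TRUE
  }
  dplyr::arrange(out, .data$subject_id, .data$block)
}

#' Mixed repeated-measures ANOVA (univariate, sphericity assumed)
#'
#' Fits the classic split-plot ANOVA with between-subject and
#' within-subject factors: the within-cell responses form a multivariate
#' linear model on the between design (sum-to-zero contrasts, Type III
#' sums of squares, so unbalanced between-group sizes are handled the
#' conventional way), and each within effect is tested univariately with
#' sphericity-assumed degrees of freedom. Partial eta squared is reported
#' as `SS_effect / (SS_effect + SS_error)`.
#'
#' @param data Long-format data frame: one row per subject x within-cell.
#' @param dv Name of the response column (e.g. a learning rate).
#' @param between Character vector of between-subject factor columns
#'   (each between cell needs at least 2 subjects).
#' @param within Character vector of within-subject factor columns; every
#'   subject must have exactly one observation in every within-cell.
#' @param subject Name of the subject identifier column.
#' @return A tibble of class `prlt_anova` with one row per effect:
#'   `effect`, `df1`, `df2`, `statistic`, `p.value`, `pes`, `note`.
#' @export
mixed_anova <- function(data, dv, between, within, subject = "subject_id") {
  for (v in c(dv, between, within, subject))
    stop_unless(v %in% names(data), paste("column not found:", v))
  data <- dplyr::mutate(data, dplyr::across(dplyr::all_of(c(between, within)),
                                            as.factor))
  # balance check: every subject x within-cell exactly once
  counts <- data |>
    dplyr::count(dplyr::across(dplyr::all_of(c(subject, within))))
  n_cells <- prod(vapply(within, function(w) length(unique(data[[w]])), numeric(1)))
  per_subj <- counts |>
    dplyr::group_by(dplyr::across(dplyr::all_of(subject))) |>
    dplyr::summarise(ok = all(.data$n == 1) && dplyr::n() == n_cells,
                     .groups = "drop")
  bad <- per_subj[[subject]][!per_subj$ok]
  stop_unless(length(bad) == 0,
              paste("unbalanced within-subject cells for:",
                    paste(bad, collapse = ", ")))
  for (b in between)
    stop_unless(length(unique(data[[b]])) >= 2,
                paste("between factor", b, "needs at least 2 levels"))
  cell_sizes <- data |>
    dplyr::filter(!duplicated(.data[[subject]])) |>
    dplyr::count(dplyr::across(dplyr::all_of(between)))
  n_between_cells <- prod(vapply(between, function(b)
    length(unique(data[[b]])), numeric(1)))
  stop_unless(nrow(cell_sizes) == n_between_cells && all(cell_sizes$n >= 2),
              "each between-subjects cell needs at least 2 subjects")

  wide <- data |>
    dplyr::select(dplyr::all_of(c(subject, between, within, dv))) |>
    tidyr::pivot_wider(names_from = dplyr::all_of(within),
                       values_from = dplyr::all_of(dv), names_sep = ".")
  resp_cols <- setdiff(names(wide), c(subject, between))
  idata <- as.data.frame(do.call(rbind, strsplit(resp_cols, ".", fixed = TRUE)))
  names(idata) <- within
  idata[] <- lapply(idata, factor)
  Y <- as.matrix(wide[, resp_cols])

  rhs <- if (length(between)) paste(between, collapse = " * ") else "1"
  contr <- stats::setNames(rep(list("contr.sum"), length(between)), between)
  mod_data <- as.data.frame(wide[, c(subject, between)])
  mod <- stats::lm(stats::as.formula(paste("Y ~", rhs)), data = mod_data,
                   contrasts = if (length(between)) contr else NULL)
  idesign <- stats::as.formula(paste("~", paste(within, collapse = " * ")))
  av <- car::Anova(mod, idata = idata, idesign = idesign, type = "III")
  um <- suppressWarnings(summary(av, multivariate = FALSE))$univariate.tests
  tbl <- tibble::tibble(
    effect = rownames(um),
    ss = unname(um[, "Sum Sq"]),
    df1 = unname(um[, "num Df"]),
    ss_error = unname(um[, "Error SS"]),
    df2 = unname(um[, "den Df"]),
    statistic = unname(um[, "F value"]),
    p.value = unname(um[, "Pr(>F)"])) |>
    dplyr::filter(.data$effect != "(Intercept)") |>
    dplyr::mutate(
      pes = .data$ss / (.data$ss + .data$ss_error),
      note = ifelse(is.finite(.data$statistic), "", "zero error variance"),
      p.value = ifelse(is.finite(.data$statistic), .data$p.value, NA_real_))
  out <- tbl[, c("effect", "df1", "df2", "statistic", "p.value", "pes", "note")]
  structure(out, class = c("prlt_anova", class(out)),
            dv = dv, between = between, within = within)
}

#' @exportS3Method generics::tidy
tidy.prlt_anova <- function(x, ...) {
  out <- x
  class(out) <- class(tibble::tibble())
  out
}

#' @exportS3Method generics::glance
glance.prlt_anova <- function(x, ...) {
  top <- x[nrow(x), ]  # last row: the highest-order interaction
  tibble::tibble(effect = top$effect, statistic = top$statistic,
                 df1 = top$df1, df2 = top$df2, p.value = top$p.value)
}

#' @export
print.prlt_anova <- function(x, ...) {
  cat(sprintf("<prlt_anova: %s ~ %s x (%s)>\n", attr(x, "dv"),
              paste(attr(x, "between"), collapse = " x "),
              paste(attr(x, "within"), collapse = " x ")))
  NextMethod()
}

#' Paired post-hoc contrasts with Benjamini-Hochberg correction
#'
#' Runs a two-sided paired t-test for every contrast in the family and
#' adjusts the p-values with the Benjamini-Hochberg step-up rule across the
#' whole family.
#'
#' @param contrasts Named list; each element is a list with numeric vectors
#'   `x` and `y` of equal length (the paired samples).
#' @return A tibble of class `prlt_posthoc`: `contrast`, `estimate` (mean of
#'   `x - y`), `statistic`, `df`, `p.value`, `p.adjusted`.
#' @export
posthoc_paired <- function(contrasts) {
  stop_unless(length(contrasts) >= 1, "empty contrast family")
  rows <- purrr::imap_dfr(contrasts, function(ct, label) {
    stop_unless(length(ct$x) == length(ct$y) && length(ct$x) >= 2,
                paste("contrast", label, "needs >= 2 pairs of equal length"))
    d <- ct$x - ct$y
    if (stats::sd(d) == 0) {
      return(tibble::tibble(contrast = label, estimate = mean(d),
                            statistic = NA_real_, df = length(d) - 1,
                            p.value = NA_real_, note = "zero variance"))
    }
    tt <- stats::t.test(ct$x, ct$y, paired = TRUE)
    tibble::tibble(contrast = label, estimate = unname(tt$estimate),
                   statistic = unname(tt$statistic),
                   df = unname(tt$parameter), p.value = tt$p.value,
                   note = "")
  })
  rows$p.adjusted <- stats::p.adjust(rows$p.value, method = "BH")
  structure(rows, class = c("prlt_posthoc", class(rows)))
}

#' Build the default observation-effect post-hoc family
#'
#' The block-1-to-block-2 learning-rate changes tested together after a
#' significant observation x PLS-label interaction: for a given
#' observation-group arm, the self and other learning rates, separately in
#' the Selfish and Prosocial label groups (4 contrasts).
#'
#' @param summary Subject summaries from [summarize_subjects()].
#' @param group Which observation arm to test (`"OBS"` or `"CON"`).
#' @return A named list of contrasts suitable for [posthoc_paired()];
#'   contrasts are block 1 minus block 2 (negative t means an increase).
#' @export
observation_posthoc_family <- function(summary, group = "OBS") {
  summary <- dplyr::filter(summary, .data$included, .data$group == !!group)
  fam <- list()
  for (lab in c("Selfish", "Prosocial")) {
    sub <- dplyr::filter(summary, .data$label == lab)
    b1 <- dplyr::filter(sub, .data$block == 1) |> dplyr::arrange(.data$subject_id)
    b2 <- dplyr::filter(sub, .data$block == 2) |> dplyr::arrange(.data$subject_id)
    for (cond in c("self", "other")) {
      fam[[paste0(group, "-", lab, ": alpha_", cond, " b1 vs b2")]] <-
        list(x = b1[[paste0("alpha_", cond)]], y = b2[[paste0("alpha_", cond)]])
    }
  }
  fam
}

#' Manipulation-check statistics for one block
#'
#' The standard battery on the subject summaries of a single block:
#' one-sample t-tests of HRP against chance (0.5) and of the learning rates
#' and inverse temperatures against 0, per condition; paired self-other
#' t-tests on HRP, z-RT, learning rate and inverse temperature; independent
#' two-group t-tests (OBS vs CON) on the same measures; and Pearson
#' correlations of PLS with the condition differences in HRP
#' (other - self) and z-RT (self - other). All two-sided. Zero-variance
#' samples are flagged instead of tested.
#'
#' @param summary Subject summaries from [summarize_subjects()].
#' @param block Which block to test (default 1, the baseline).
#' @return A tidy tibble: `test`, `measure`, `estimate`, `statistic`, `df`,
#'   `p.value`, `note`.
#' @export
basic_tests <- function(summary, block = 1) {
  s <- dplyr::filter(summary, .data$included, .data$block == !!block)
  safe_t <- function(test, measure, x, y = NULL, mu = 0, paired = FALSE) {
    flat <- if (is.null(y)) stats::sd(x) == 0 else
      (paired && stats::sd(x - y) == 0) || (!paired && stats::sd(c(x, y)) == 0)
    if (is.na(flat) || flat) {
      return(tibble::tibble(test = test, measure = measure,
                            estimate = mean(x) - if (is.null(y)) mu else mean(y),
                            statistic = NA_real_, df = NA_real_,
                            p.value = NA_real_, note = "zero variance"))
    }
    tt <- if (is.null(y)) stats::t.test(x, mu = mu) else
      stats::t.test(x, y, paired = paired, var.equal = FALSE)
    tibble::tibble(test = test, measure = measure,
                   estimate = unname(tt$estimate[1]) -
                     (if (is.null(y)) mu else
                        if (paired) 0 else unname(tt$estimate[2])),
                   statistic = unname(tt$statistic), df = unname(tt$parameter),
                   p.value = tt$p.value, note = "")
  }
  rows <- list()
  for (cond in c("self", "other")) {
    rows <- c(rows, list(
      safe_t("one-sample vs 0.5", paste0("hrp_", cond), s[[paste0("hrp_", cond)]], mu = 0.5),
      safe_t("one-sample vs 0", paste0("alpha_", cond), s[[paste0("alpha_", cond)]]),
      safe_t("one-sample vs 0", paste0("tau_", cond), s[[paste0("tau_", cond)]])))
  }
  for (m in c("hrp", "zrt", "alpha", "tau")) {
    rows <- c(rows, list(
      safe_t("paired self vs other", m, s[[paste0(m, "_self")]],
             s[[paste0(m, "_other")]], paired = TRUE)))
  }
  obs <- dplyr::filter(s, .data$group == "OBS")
  con <- dplyr::filter(s, .data$group == "CON")
  for (m in c("hrp_self", "hrp_other", "zrt_self", "zrt_other",
              "alpha_self", "alpha_other", "tau_self", "tau_other")) {
    rows <- c(rows, list(safe_t("OBS vs CON", m, obs[[m]], con[[m]])))
  }
  safe_cor <- function(measure, x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(tibble::tibble(test = "correlation with PLS", measure = measure,
                            estimate = NA_real_, statistic = NA_real_,
                            df = NA_real_, p.value = NA_real_,
                            note = "zero variance"))
    }
    ct <- stats::cor.test(x, y)
    tibble::tibble(test = "correlation with PLS", measure = measure,
                   estimate = unname(ct$estimate), statistic = unname(ct$statistic),
                   df = unname(ct$parameter), p.value = ct$p.value, note = "")
  }
  rows <- c(rows, list(
    safe_cor("hrp_other - hrp_self", s$pls, s$hrp_other - s$hrp_self),
    safe_cor("zrt_self - zrt_other", s$pls, s$zrt_self - s$zrt_other)))
  dplyr::bind_rows(rows)
}

#' Percentile bootstrap of a between-group mean difference
#'
#' Resamples both groups with replacement `n_boot` times, forms the
#' bootstrap distribution of `mean(a) - mean(b)`, and reports the percentile
#' 95% interval and a two-sided p-value (twice the smaller tail proportion
#' of the bootstrap distribution on either side of zero).
#'
#' @param a,b Numeric samples.
#' @param n_boot Number of resamples (default 1000; fewer than 100 raises a
#'   warning).
#' @param seed Optional integer seed; given the seed the result is exactly
#'   reproducible.
#' @return A list of class `prlt_boot`: `estimate`, `ci` (2.5/97.5
#'   percentiles), `p.value`, `n_boot`. `tidy()` returns it as a one-row
#'   tibble.
#' @export
bootstrap_diff <- function(a, b, n_boot = 1000, seed = NULL) {
  stop_unless(length(a) >= 1 && length(b) >= 1, "samples must be non-empty")
  if (n_boot < 100) warning("n_boot < 100: bootstrap p unstable")
  if (!is.null(seed)) set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(i)
    mean(sample(a, replace = TRUE)) - mean(sample(b, replace = TRUE)),
    numeric(1))
  p <- 2 * min(mean(boots <= 0), mean(boots >= 0))
  structure(list(estimate = mean(a) - mean(b),
                 ci = stats::quantile(boots, c(0.025, 0.975), names = FALSE),
                 p.value = min(p, 1), n_boot = n_boot),
            class = "prlt_boot")
}

#' @exportS3Method generics::tidy
tidy.prlt_boot <- function(x, ...) {
  tibble::tibble(estimate = x$estimate, conf.low = x$ci[1],
                 conf.high = x$ci[2], p.value = x$p.value, n_boot = x$n_boot)
}

#' @export
print.prlt_boot <- function(x, ...) {
  cat(sprintf("<prlt_boot: diff = %.4f, 95%% CI [%.4f, %.4f], p = %.4f (%d resamples)>\n",
              x$estimate, x$ci[1], x$ci[2], x$p.value, x$n_boot))
  invisible(x)
}
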