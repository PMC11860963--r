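trial_col_types <- function() {
  readr::cols(
    subject_id = readr::col_character(),
    group = readr::col_character(),
    block = readr::col_integer(),
    trial = readr::col_integer(),
    condition = readr::col_character(),
    chosen = readr::col_character(),
    chose_high = readr::col_integer(),
    reward = readr::col_integer(),
    rt_ms = readr::col_double())
}

#' Validate a trial table
#'
#' Checks the schema used throughout the package: required columns; `group`
#' in \{OBS, CON\}; `condition` in \{self, other\}; `chosen` in
#' \{a, b, NA\}; `chose_high`/`reward` in \{0, 1\} and `NA` exactly when
#' `chosen` is `NA`; positive reaction times (or `NA`); unique
#' (subject, block, trial) keys. Violations are reported with row numbers.
#'
#' @param x A data frame.
#' @return `x` (as a tibble), invisibly valid; otherwise an error listing
#'   the offending rows.
#' @export
validate_trials <- function(x) {
  required <- c("subject_id", "group", "block", "trial", "condition",
                "chosen", "chose_high", "reward", "rt_ms")
  miss <- setdiff(required, names(x))
  stop_unless(length(miss) == 0,
              paste("missing columns:", paste(miss, collapse = ", ")))
  x <- tibble::as_tibble(x)
  bad <- function(rows, what) {
    if (any(rows, na.rm = TRUE))
      paste0(what, " (rows ", paste(utils::head(which(rows), 5), collapse = ", "),
             if (sum(rows, na.rm = TRUE) > 5) ", ..." else "", ")")
  }
  na_chosen <- is.na(x$chosen)
  problems <- c(
    bad(!x$group %in% c("OBS", "CON"), "unknown group value"),
    bad(!x$condition %in% c("self", "other"), "unknown condition value"),
    bad(!na_chosen & !x$chosen %in% c("a", "b"), "chosen must be a/b/NA"),
    bad(!na_chosen & (is.na(x$reward) | !x$reward %in% c(0L, 1L)),
        "reward must be 0/1 when a choice was made"),
    bad(na_chosen & !is.na(x$reward), "reward present without a choice"),
    bad(!na_chosen & (is.na(x$chose_high) | !x$chose_high %in% c(0L, 1L)),
        "chose_high must be 0/1 when a choice was made"),
    bad(na_chosen & !is.na(x$chose_high), "chose_high present without a choice"),
    bad(!is.na(x$rt_ms) & x$rt_ms <= 0, "rt_ms must be positive"),
    bad(duplicated(x[, c("subject_id", "block", "trial")]),
        "duplicate (subject, block, trial)"))
  problems <- problems[!vapply(problems, is.null, logical(1))]
  stop_unless(length(problems) == 0,
              paste("invalid trial table:", paste(unlist(problems), collapse = "; ")))
  invisible(x)
}

#' Read or write the trial-table CSV
#'
#' The interchange format: comma-separated, UTF-8, literal `NA` for missing
#' values, 1-based block and trial indices. Reading validates the schema
#' (see [validate_trials()]); an empty file with a valid header gives an
#' empty table with a warning.
#'
#' @param path File path.
#' @param x A trial table.
#' @return `read_trials()` returns the validated tibble; `write_trials()`
#'   returns `x` invisibly.
#' @export
read_trials <- function(path) {
  stop_unless(file.exists(path), paste("file not found:", path))
  x <- readr::read_csv(path, col_types = trial_col_types(), na = "NA")
  if (nrow(x) == 0) {
    warning("empty trial table: ", path)
    return(tibble::as_tibble(x))
  }
  validate_trials(x)
  x
}

#' @rdname read_trials
#' @export
write_trials <- function(x, path) {
  validate_trials(x)
  readr::write_csv(x, path, na = "NA")
  invisible(x)
}

#' Assemble or load a full pipeline configuration
#'
#' Bundles the task, cohort, fitting and analysis settings plus one global
#' seed. Every stochastic stage of [run_pipeline()] draws its own substream
#' seed deterministically from the global seed (`seed + 97 * stage_index`,
#' reduced modulo 2^31 - 1), so stages are independently reproducible.
#' `read_run_config()` reads the same structure from a YAML file whose keys
#' mirror the argument names (`task:`, `cohort:`, `fit:`, `analysis:`,
#' `seed:`).
#'
#' @param task List of [task_config()] arguments.
#' @param cohort List of [cohort_spec()] arguments.
#' @param fit List of fitting settings: `models`, `tau_max`, `v0`,
#'   `n_refine`.
#' @param analysis List of analysis settings: `n_sims` (PPC), `grid_n_sims`,
#'   `n_boot`.
#' @param seed Global integer seed.
#' @return A list of class `prlt_config`.
#' @export
run_config <- function(task = list(), cohort = list(), fit = list(),
                       analysis = list(), seed = 1L) {
  fit_defaults <- list(models = c("M0", "M1", "M2"), tau_max = 20, v0 = 0.5,
                       n_refine = 3)
  ana_defaults <- list(n_sims = 1000, grid_n_sims = 1000, n_boot = 1000)
  structure(list(
    task = do.call(task_config, task),
    cohort = do.call(cohort_spec, cohort),
    fit = utils::modifyList(fit_defaults, fit),
    analysis = utils::modifyList(ana_defaults, analysis),
    seed = as.integer(seed)),
    class = "prlt_config")
}

#' @rdname run_config
#' @param path Path to a YAML configuration file.
#' @examples
#' cfg <- read_run_config(system.file("extdata", "example-config.yml",
#'                                    package = "prlt"))
#' cfg$task$trials_per_condition
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  run_config(task = raw$task %||% list(), cohort = raw$cohort %||% list(),
             fit = raw$fit %||% list(), analysis = raw$analysis %||% list(),
             seed = raw$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

substream <- function(seed, stage_index) {
  as.integer((as.numeric(seed) + 97 * stage_index) %% (2^31 - 1))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Chains every stage on a synthetic cohort: build the schedule, sample the
#' cohort, fit M0/M1/M2 per subject and block, compare models by summed
#' BIC, apply the exclusion rules, run posterior predictive checks and the
#' grid simulation, summarize subjects, and run the group statistics
#' (3-way and 4-way mixed ANOVAs, FDR post-hocs, the bootstrap robustness
#' check, and the manipulation-check battery). Any stage failure aborts
#' with the stage name and cause. The PLS-split analyses need at least two
#' included subjects per observation x label cell; when a (tiny) cohort
#' cannot support them they are returned as a `"skipped: ..."` note rather
#' than aborting.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, the main tables are also
#'   written there as CSV (plus the config and seed as YAML for
#'   provenance).
#' @return A list of class `prlt_report` with elements `schedule`, `cohort`,
#'   `fits`, `comparison`, `exclusions`, `ppc`, `grid`, `summary`,
#'   `anova3`, `anova4`, `posthoc`, `bootstrap`, `basic`, `config`, `seeds`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "prlt_config"))
  seeds <- stats::setNames(
    lapply(1:6, function(i) substream(config$seed, i)),
    c("cohort", "ppc", "grid", "boot", "anova", "misc"))

  schedule <- stage("schedule", build_schedule(config$task))
  cohort <- stage("simulate",
                  sample_cohort(config$cohort, config$task, seed = seeds$cohort,
                                v0 = config$fit$v0))
  fits <- stage("fit",
                fit_cohort(cohort$trials, models = config$fit$models,
                           tau_max = config$fit$tau_max, v0 = config$fit$v0,
                           n_refine = config$fit$n_refine))
  comparison <- stage("compare",
                      compare_models(fits, setdiff(config$fit$models, "M0")))
  exclusions <- stage("exclusions", apply_exclusions(cohort$trials, fits))
  ppc <- stage("ppc",
               posterior_predictive(fits, cohort$trials, schedule,
                                    n_sims = config$analysis$n_sims,
                                    seed = seeds$ppc, v0 = config$fit$v0))
  grid <- stage("grid",
                grid_predictiveness(schedule,
                                    n_sims = config$analysis$grid_n_sims,
                                    seed = seeds$grid, v0 = config$fit$v0))
  summary <- stage("summaries",
                   summarize_subjects(cohort$trials, fits, exclusions))
  basic <- stage("basic-tests", basic_tests(summary))
  inc <- dplyr::filter(summary, .data$included)
  long <- tidyr::pivot_longer(
    inc, dplyr::all_of(c("alpha_self", "alpha_other")),
    names_to = "reward", names_prefix = "alpha_", values_to = "alpha")
  anova3 <- stage("anova-3way",
                  mixed_anova(long, "alpha", between = "group",
                              within = c("block", "reward")))
  cells4 <- long |>
    dplyr::filter(!duplicated(.data$subject_id)) |>
    dplyr::count(.data$group, .data$label)
  anova4 <- if (nrow(cells4) == 4 && all(cells4$n >= 2)) {
    stage("anova-4way",
          mixed_anova(long, "alpha", between = c("group", "label"),
                      within = c("block", "reward")))
  } else {
    "skipped: fewer than 2 included subjects in some observation x label cell"
  }
  posthoc <- tryCatch(
    posthoc_paired(observation_posthoc_family(summary, "OBS")),
    error = function(e) paste("skipped:", conditionMessage(e)))
  boot <- stage("bootstrap", {
    d_aself <- inc |>
      dplyr::select("subject_id", "group", "label", "block", "alpha_self") |>
      tidyr::pivot_wider(names_from = "block", values_from = "alpha_self",
                         names_prefix = "b") |>
      dplyr::filter(.data$label == "Prosocial") |>
      dplyr::mutate(d = .data$b2 - .data$b1)
    a <- d_aself$d[d_aself$group == "OBS"]
    b <- d_aself$d[d_aself$group == "CON"]
    if (length(a) >= 2 && length(b) >= 2) {
      bootstrap_diff(a, b, n_boot = config$analysis$n_boot, seed = seeds$boot)
    } else {
      "skipped: too few prosocial subjects for the bootstrap"
    }
  })

  report <- structure(
    list(schedule = schedule, cohort = cohort, fits = fits,
         comparison = comparison, exclusions = exclusions, ppc = ppc,
         grid = grid, summary = summary, anova3 = anova3, anova4 = anova4,
         posthoc = posthoc, bootstrap = boot, basic = basic,
         config = config, seeds = seeds),
    class = "prlt_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_trials(report$cohort$trials, file.path(out_dir, "trials.csv"))
  readr::write_csv(report$cohort$truth, file.path(out_dir, "truth.csv"))
  readr::write_csv(report$fits, file.path(out_dir, "fits.csv"))
  readr::write_csv(report$comparison, file.path(out_dir, "model_comparison.csv"))
  readr::write_csv(report$exclusions, file.path(out_dir, "exclusions.csv"))
  readr::write_csv(tibble::as_tibble(report$ppc), file.path(out_dir, "ppc.csv"))
  readr::write_csv(tibble::as_tibble(report$grid), file.path(out_dir, "grid.csv"))
  readr::write_csv(report$summary, file.path(out_dir, "subject_summary.csv"))
  readr::write_csv(report$basic, file.path(out_dir, "basic_tests.csv"))
  for (nm in c("anova3", "anova4")) {
    if (inherits(report[[nm]], "prlt_anova"))
      readr::write_csv(tidy(report[[nm]]), file.path(out_dir, paste0(nm, ".csv")))
  }
  if (inherits(report$posthoc, "prlt_posthoc"))
    readr::write_csv(tibble::as_tibble(report$posthoc),
                     file.path(out_dir, "posthoc.csv"))
  prov <- list(seed = report$config$seed,
               substreams = report$seeds,
               task = unclass(report$config$task),
               fit = report$config$fit,
               analysis = report$config$analysis,
               grid = list(r_alpha = attr(report$grid, "r_alpha"),
                           r_tau = attr(report$grid, "r_tau")))
  yaml::write_yaml(prov, file.path(out_dir, "provenance.yml"))
  invisible(report)
}

#' @export
print.prlt_report <- function(x, ...) {
  cat("<prlt_report>\n")
  cat("  subjects:", length(unique(x$cohort$trials$subject_id)),
      " included:", sum(x$exclusions$included), "\n")
  cat("  model comparison (summed BIC):\n")
  print(x$comparison)
  if (inherits(x$anova4, "prlt_anova")) {
    top <- x$anova4[nrow(x$anova4), ]
    cat(sprintf("  4-way interaction: F(%g, %g) = %.3f, p = %.4f\n",
                top$df1, top$df2, top$statistic, top$p.value))
  }
  invisible(x)
}
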