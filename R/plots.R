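#' @exportS3Method ggplot2::autoplot
autoplot.prlt_schedule <- function(object, ...) {
  df <- tibble::as_tibble(unclass_schedule(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$within_condition_index,
                                   y = .data$p_arm_a,
                                   colour = .data$condition)) +
    ggplot2::geom_step() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$block)) +
    ggplot2::labs(x = "within-condition trial", y = "P(reward | arm a)",
                  colour = "condition") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.prlt_grid <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$alpha, y = .data$tau,
                               fill = .data$mean_hrp)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "mean HRP") +
    ggplot2::labs(
      x = expression(alpha), y = expression(tau),
      subtitle = sprintf("r(alpha, HRP) = %.2f, r(tau, HRP) = %.2f",
                         attr(object, "r_alpha"), attr(object, "r_tau"))) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.prlt_ppc <- function(object, ...) {
  r <- glance(object)$r
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$actual_hrp, y = .data$predicted_hrp,
                               colour = .data$condition)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "actual HRP", y = "predicted HRP",
                  subtitle = sprintf("r = %.2f", r)) +
    ggplot2::theme_minimal()
}

#' Plot the block-1 PLS distribution by observation group
#'
#' Histogram of prosocial learning sensitivity (`alpha_other - alpha_self`)
#' in block 1; the dashed line at zero is the Selfish/Prosocial boundary.
#'
#' @param summary Subject summaries from [summarize_subjects()].
#' @return A ggplot object.
#' @export
plot_pls <- function(summary) {
  b1 <- dplyr::filter(summary, .data$block == 1, .data$included)
  ggplot2::ggplot(b1, ggplot2::aes(x = .data$pls, fill = .data$group)) +
    ggplot2::geom_histogram(position = "identity", alpha = 0.55, bins = 25) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "PLS (block 1)", y = "subjects", fill = "group") +
    ggplot2::theme_minimal()
}

#' Plot learning rates by block, condition and label group
#'
#' Mean fitted learning rate (with standard-error bars) per block and
#' reward condition, split by observation group and Selfish/Prosocial
#' label -- the pattern the 4-way interaction tests.
#'
#' @param summary Subject summaries from [summarize_subjects()].
#' @return A ggplot object.
#' @export
plot_learning_rates <- function(summary) {
  long <- summary |>
    dplyr::filter(.data$included) |>
    tidyr::pivot_longer(dplyr::all_of(c("alpha_self", "alpha_other")),
                        names_to = "reward", names_prefix = "alpha_",
                        values_to = "alpha") |>
    dplyr::group_by(.data$group, .data$label, .data$block, .data$reward) |>
    dplyr::summarise(mean_alpha = mean(.data$alpha),
                     se = stats::sd(.data$alpha) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$block),
                                     y = .data$mean_alpha,
                                     colour = .data$reward,
                                     group = .data$reward)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean_alpha - .data$se,
                                          ymax = .data$mean_alpha + .data$se)) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$group),
                        cols = ggplot2::vars(.data$label)) +
    ggplot2::labs(x = "block", y = expression(alpha), colour = "reward") +
    ggplot2::theme_minimal()
}
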