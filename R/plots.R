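# ggplot2 views of the result tables, mirroring the standard displays for
# this analysis: daily accuracy with its regression line, per-class
# precision/recall curves, stacked threshold-count bars colored by true
# label, and the cross-validation accuracy band of the cascade.

#' Plot daily accuracy with its trend line
#'
#' @param series Tibble (`day_index`, `accuracy`) from [daily_accuracy()].
#' @param trend Overlay the least-squares trend (default `TRUE`).
#' @return A ggplot.
#' @export
plot_daily_accuracy <- function(series, trend = TRUE) {
  p <- ggplot2::ggplot(series,
                       ggplot2::aes(x = .data$day_index,
                                    y = .data[[names(series)[2]]])) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "treatment day", y = names(series)[2]) +
    ggplot2::theme_minimal()
  if (trend) {
    fit <- fit_trend(series)
    p <- p + ggplot2::geom_abline(slope = fit$slope,
                                  intercept = fit$intercept,
                                  color = "steelblue")
  }
  p
}

#' Plot per-class precision and recall over treatment days
#'
#' @param pr Tibble from [precision_recall()].
#' @return A ggplot, faceted by metric.
#' @export
plot_precision_recall <- function(pr) {
  long <- tidyr::pivot_longer(pr, c("precision", "recall"),
                              names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$day_index,
                                     y = .data$value,
                                     color = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, ncol = 1) +
    ggplot2::labs(x = "treatment day", y = NULL, color = "true class") +
    ggplot2::theme_minimal()
}

#' Stacked bars of patients above a probability threshold
#'
#' Bars count, per day, patients whose predicted probability for the
#' target class exceeds the threshold, stacked by true outcome so true and
#' false positives are visible at a glance.
#'
#' @param counts Tibble from [threshold_counts()].
#' @return A ggplot.
#' @export
plot_threshold_counts <- function(counts) {
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$day_index, y = .data$n,
                                       fill = .data$true_label)) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "treatment day", y = "patients above threshold",
      fill = "true outcome",
      title = sprintf("p(%s) > %.2f", counts$target_class[1],
                      counts$threshold[1])
    ) +
    ggplot2::theme_minimal()
}

#' Cross-validation accuracy of a day-model cascade
#'
#' Mean five-fold accuracy per treatment day with a +/- one standard
#' deviation ribbon.
#'
#' @param object A `day_model_list`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.day_model_list <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$day_index,
                                  y = .data$cv_mean_accuracy)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$cv_mean_accuracy - .data$cv_std_accuracy,
                   ymax = .data$cv_mean_accuracy + .data$cv_std_accuracy),
      fill = "steelblue", alpha = 0.2) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = "treatment day", y = "CV mean accuracy") +
    ggplot2::theme_minimal()
}
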