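#' Plot a size or Small% series with its linear trend
#'
#' @param data Series tibble with `lagged_month` and a value column.
#' @param value Value column (tidy-eval).
#' @param colour Optional grouping column mapped to colour.
#' @param trend Overlay the OLS trend line.
#' @param log_scale Log-scale the y axis (natural for biovolumes).
#' @return A ggplot object.
#' @export
plot_size_series <- function(data, value = biovolume, colour = NULL,
                             trend = TRUE, log_scale = FALSE) {
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$lagged_month,
                                          y = {{ value }},
                                          colour = {{ colour }})) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = "Lagged month", y = rlang::as_name(rlang::enquo(value)))
  if (trend) {
    p <- p + ggplot2::geom_smooth(method = "lm", formula = y ~ x,
                                  se = FALSE, linewidth = 0.7)
  }
  if (log_scale) p <- p + ggplot2::scale_y_log10()
  p
}

#' @exportS3Method ggplot2::autoplot
autoplot.decomposition_result <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("time", "value", "trend", "seasonal",
                                "residual")],
    cols = -"time", names_to = "component", values_to = "y")
  long$component <- factor(long$component,
                           levels = c("value", "trend", "seasonal",
                                      "residual"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$y)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$component),
                        scales = "free_y") +
    ggplot2::labs(x = "Lagged month", y = NULL)
}

#' @exportS3Method ggplot2::autoplot
autoplot.shapley_matrix <- function(object, ...) {
  imp <- global_importance(object)
  ggplot2::ggplot(imp, ggplot2::aes(x = .data$importance,
                                    y = stats::reorder(.data$feature,
                                                       .data$importance))) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Mean |Shapley value|", y = NULL)
}

#' @exportS3Method ggplot2::autoplot
autoplot.partition_result <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("scope_id", "within_species",
                                "composition")],
    cols = -"scope_id", names_to = "component", values_to = "change")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$scope_id, y = .data$change,
                                     fill = .data$component)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::geom_point(
      data = tibble::as_tibble(object),
      ggplot2::aes(x = .data$scope_id, y = .data$delta_c),
      inherit.aes = FALSE, shape = 21, fill = "white") +
    ggplot2::labs(x = NULL, y = "Change in community mean size (um^3)")
}

#' @exportS3Method ggplot2::autoplot
autoplot.tournament_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$learner,
                                                      .data$r_squared),
                                   y = .data$r_squared,
                                   fill = .data$winner)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Held-out R\u00b2")
}
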