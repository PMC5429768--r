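#' Plot fitted Golgi gates over exemplar features
#'
#' Scatter of Threshold-60 minor axis intensity vs area with the fitted
#' gate boundaries; optionally colored by exemplar labels.
#'
#' @param object A `golgi_gates` object.
#' @param table Optional feature table to overlay as points.
#' @param labels Optional class labels for coloring the points.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.golgi_gates <- function(object, table = NULL, labels = NULL, ...) {
  b <- object$boundaries
  p <- ggplot2::ggplot()
  if (!is.null(table)) {
    df <- tibble::tibble(
      x = table$golgi_t60_minor_axis_intensity,
      y = table$golgi_t60_area,
      label = if (is.null(labels)) "cell" else as.character(labels))
    p <- p + ggplot2::geom_point(
      data = df,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$label),
      alpha = 0.5, size = 0.8)
  }
  p +
    ggplot2::geom_vline(xintercept = c(b$x_intact_max, b$x_full_min),
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = c(b$y_intact_max, b$y_full_min),
                        linetype = "dashed") +
    ggplot2::labs(x = "Threshold-60 minor axis intensity (um)",
                  y = "Threshold-60 area (um^2)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Density dot-plot of a feature pair
#'
#' @param data A [density_plot_data()] tibble.
#' @return A ggplot object (tile heat map; zero-count bins blank).
#' @export
plot_density_map <- function(data) {
  feats <- attr(data, "features")
  df <- data[data$count > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x_mid, y = .data$y_mid,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(trans = "log10") +
    ggplot2::labs(x = feats[["x"]], y = feats[["y"]], fill = "cells") +
    ggplot2::theme_minimal()
}

#' Stacked bars of Golgi morphology percentages per sample
#'
#' @param summaries Tibble of [summarize_population()] rows.
#' @return A ggplot object.
#' @export
plot_population_summary <- function(summaries) {
  long <- tidyr::pivot_longer(
    summaries[, c("sample_id", "pct_intact", "pct_partial", "pct_full")],
    cols = -"sample_id", names_to = "population", values_to = "pct")
  long$population <- factor(sub("pct_", "", long$population),
                            levels = c("full", "partial", "intact"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id, y = .data$pct,
                                     fill = .data$population)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "% of eligible cells", fill = "Golgi") +
    ggplot2::theme_minimal()
}
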