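#' Plot a scan image
#'
#' Renders the pixel raster with ggplot2; overlays caliper or crop boxes
#' when supplied.
#'
#' @param object A `scan_image`.
#' @param boxes Optional tibble of boxes (`x_left`, `y_top`, `x_right`,
#'   `y_bottom`) to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot scan_image
#' @export
autoplot.scan_image <- function(object, boxes = NULL, ...) {
  g <- to_grayscale(object)
  df <- tidyr::expand_grid(y = seq_len(g$height) - 1L, x = seq_len(g$width) - 1L)
  df$value <- as.vector(t(g$pixels))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 255)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(fill = "intensity") +
    ggplot2::theme_void()
  if (!is.null(boxes) && nrow(boxes) > 0) {
    p <- p + ggplot2::geom_rect(
      data = boxes, inherit.aes = FALSE, color = "red", fill = NA, linewidth = 0.4,
      ggplot2::aes(xmin = .data$x_left, xmax = .data$x_right,
                   ymin = .data$y_top, ymax = .data$y_bottom))
  }
  p
}

#' Plot a per-task score table
#'
#' Bar chart of sensitivity, specificity and F1 per task, the layout used
#' for detector-performance summaries.
#'
#' @param object A `bus_score_table` from [score_manifest()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bus_score_table
#' @export
autoplot.bus_score_table <- function(object, ...) {
  long <- tidyr::pivot_longer(object,
                              cols = c("sensitivity", "specificity", "f1"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$task, y = .data$value,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
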