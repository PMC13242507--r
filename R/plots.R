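#' Plot accuracy estimates against their chance level
#'
#' Point estimates with CI error bars per cell, faceted by proportion when
#' present, with a dashed line at the chance level of the index.
#'
#' @param object A `blend_accuracy` tibble from [aggregate_accuracy()]
#'   (one index).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.blend_accuracy <- function(object, ...) {
  x_var <- if ("combination" %in% names(object)) "combination" else "index"
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data[[x_var]], y = .data$mean)) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$chance),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high,
                                          colour = .data$above_chance)) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(y = "proportion correct", x = NULL,
                  colour = "above chance",
                  title = unique(object$index)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if ("proportion" %in% names(object)) {
    p <- p + ggplot2::facet_wrap(~proportion)
  }
  p
}

#' Heatmap of mean ratings per combination, proportion and scale
#'
#' @param cell_means Output of [cell_mean_ratings()].
#' @return A ggplot object.
#' @export
plot_cell_means <- function(cell_means) {
  ggplot2::ggplot(cell_means,
                  ggplot2::aes(x = .data$scale, y = .data$combination,
                               fill = .data$mean)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~proportion) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 10)) +
    ggplot2::labs(x = "rating scale", y = NULL, fill = "mean rating") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
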