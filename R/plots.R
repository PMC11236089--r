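#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_tile geom_hline
#'   labs scale_y_reverse coord_equal theme_minimal facet_wrap
#' @export
ggplot2::autoplot

#' Plot spot labels in tissue coordinates
#'
#' Scatter of spots at their micron coordinates, coloured by assigned label.
#' Uses the image convention (y increases downward), so the plot matches the
#' slide orientation.
#'
#' @param result a `spot_annotation` tibble.
#' @param geometry a `spot_geometry` tibble with matching barcodes.
#' @return a ggplot object.
#' @export
plot_spot_labels <- function(result, geometry) {
  df <- dplyr::inner_join(
    tibble::as_tibble(result),
    tibble::as_tibble(geometry),
    by = c(spot_id = "barcode")
  )
  ggplot(df, aes(x = .data$x_um, y = .data$y_um, colour = .data$assigned_label)) +
    geom_point(size = 1.5) +
    scale_y_reverse() +
    coord_equal() +
    labs(x = "x (µm)", y = "y (µm)", colour = "cell type") +
    theme_minimal()
}

#' @export
autoplot.sctype_scores <- function(object, ...) {
  tidy(object) |>
    ggplot(aes(x = .data$spot_id, y = .data$cell_type, fill = .data$score)) +
    geom_tile() +
    labs(x = "spot", y = "cell type", fill = "enrichment") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' @export
autoplot.benchmark_report <- function(object, ...) {
  tidy(object) |>
    tidyr::pivot_longer(c("precision", "recall", "f1"),
                        names_to = "metric", values_to = "value") |>
    ggplot(aes(x = .data$metric, y = .data$value)) +
    geom_point(aes(colour = .data$class), size = 2) +
    geom_hline(yintercept = attr(object, "median_f1"), linetype = "dashed") +
    labs(y = "score", x = NULL, colour = "cell type",
         caption = sprintf("dashed line: median F1 = %.3f", attr(object, "median_f1"))) +
    theme_minimal()
}
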