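# ggplot2 visualisations: spatial maps (red = high, turquoise = low),
# cell scattergrams, and per-group patient summaries.

#' @describeIn density_map autoplot method for spatial maps: raster heatmap
#'   with the red-high / turquoise-low palette; no-data cells are blank.
#' @param object a `spatial_map`.
#' @param ... unused.
#' @export
autoplot.spatial_map <- function(object, ...) {
  df <- expand.grid(y_um = object$grid_y, x_um = object$grid_x)
  df$value <- as.vector(object$values)
  ggplot2::ggplot(df, ggplot2::aes(.data$x_um, .data$y_um, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "turquoise3", high = "red2",
                                 na.value = "grey95",
                                 name = object$field %||% object$semantics) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  title = object$semantics) +
    ggplot2::theme_minimal()
}

#' Scattergram of cell coordinates coloured by a per-cell field
#'
#' @param cells cell table.
#' @param field column to colour by (default `quotient`).
#' @return A ggplot.
#' @export
plot_cell_map <- function(cells, field = "quotient") {
  ggplot2::ggplot(cells,
                  ggplot2::aes(.data$x_um, .data$y_um,
                               colour = .data[[field]])) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_gradient(low = "turquoise3", high = "red2") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
}

#' Per-patient group comparison plot for one summary measure
#'
#' Dots are mean patient values, boxes the group median and IQR — the usual
#' presentation for patient-level cohort comparisons.
#'
#' @param summaries patient-summary tibble with a `group` column.
#' @param measure summary column to plot.
#' @return A ggplot faceted by compartment.
#' @export
plot_group_measure <- function(summaries, measure = "mean_mrna_corr") {
  df <- summaries[!is.na(summaries[[measure]]), ]
  ggplot2::ggplot(df, ggplot2::aes(.data$group, .data[[measure]],
                                   colour = .data$group)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_jitter(width = 0.15, size = 1.6, alpha = 0.8) +
    ggplot2::facet_wrap(~compartment, scales = "free_y") +
    ggplot2::labs(x = NULL, y = measure) +
    ggplot2::theme_bw() +
    ggplot2::theme(legend.position = "none")
}

#' Heatmap of ranked CPA3-high marker genes
#'
#' @param expr log-normalised genes x cells matrix (mast cells).
#' @param markers ranked marker tibble from [rank_markers()].
#' @param labels CPA3 class tibble from [split_cpa3()].
#' @return A ggplot tile heatmap, cells grouped by class, genes in rank
#'   order.
#' @export
plot_marker_heatmap <- function(expr, markers, labels) {
  ord <- order(labels$cpa3_class, decreasing = TRUE)
  cells <- labels$cell_id[ord]
  gm <- as.matrix(expr[markers$gene, cells, drop = FALSE])
  df <- expand.grid(gene = factor(markers$gene, levels = rev(markers$gene)),
                    cell = factor(cells, levels = cells))
  df$value <- as.vector(gm)
  ggplot2::ggplot(df, ggplot2::aes(.data$cell, .data$gene,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "log-norm") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.ticks.x = ggplot2::element_blank()) +
    ggplot2::labs(x = "mast cells (CPA3-high then low)", y = NULL)
}
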