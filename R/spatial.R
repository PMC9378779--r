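# Spatial maps: Gaussian kernel density of mast cells, kernel-smoothed local
# means of per-cell fields (mRNA/protein quotient), density-weighted
# expression maps, and spatial ROI comparisons.

new_spatial_map <- function(values, grid_x, grid_y, semantics, bandwidth_um,
                            grid_um, field = NULL) {
  structure(list(values = values, grid_x = grid_x, grid_y = grid_y,
                 semantics = semantics, bandwidth_um = bandwidth_um,
                 grid_um = grid_um, field = field),
            class = "spatial_map")
}

#' @export
print.spatial_map <- function(x, ...) {
  cat(sprintf("<spatial_map> %s%s: %d x %d cells of %g um, bandwidth %g um\n",
              x$semantics, if (is.null(x$field)) "" else paste0("(", x$field, ")"),
              length(x$grid_y), length(x$grid_x), x$grid_um, x$bandwidth_um))
  invisible(x)
}

map_grid <- function(cells, grid_um, bounds) {
  if (is.null(bounds)) {
    bounds <- c(floor(min(cells$x_um) - 2 * grid_um),
                ceiling(max(cells$x_um) + 2 * grid_um),
                floor(min(cells$y_um) - 2 * grid_um),
                ceiling(max(cells$y_um) + 2 * grid_um))
  }
  list(x = seq(bounds[1] + grid_um / 2, bounds[2], by = grid_um),
       y = seq(bounds[3] + grid_um / 2, bounds[4], by = grid_um))
}

# kernel weight matrix: rows = grid nodes (y-major), cols = cells
kernel_weights <- function(cells, gx, gy, bandwidth_um) {
  dx2 <- outer(gx, cells$x_um, function(g, c) (g - c)^2)
  dy2 <- outer(gy, cells$y_um, function(g, c) (g - c)^2)
  # expand to the full grid: W[(iy, ix), cell]
  ny <- length(gy); nx <- length(gx)
  w <- matrix(0, ny * nx, nrow(cells))
  for (ix in seq_len(nx)) {
    w[(ix - 1) * ny + seq_len(ny), ] <-
      exp(-(sweep(dy2, 2, dx2[ix, ], "+")) / (2 * bandwidth_um^2))
  }
  w
}

#' Mast-cell density map
#'
#' Gaussian kernel density of cell coordinates on a regular grid, scaled to
#' cells per grid cell so the grid sum approximates the number of cells
#' (mass conservation, up to boundary loss).
#'
#' @param cells cell table (needs `x_um`, `y_um`; >= 1 cell).
#' @param grid_um grid cell edge (micrometres).
#' @param bandwidth_um Gaussian kernel bandwidth (micrometres).
#' @param bounds optional `c(xmin, xmax, ymin, ymax)`; defaults to the cell
#'   bounding box padded by two grid cells.
#' @return A `spatial_map` with `density` semantics.
#' @export
density_map <- function(cells, grid_um = 50, bandwidth_um = 150, bounds = NULL) {
  if (nrow(cells) == 0) {
    abort("density map needs at least one cell",
          class = "mastmap_degenerate_error")
  }
  g <- map_grid(cells, grid_um, bounds)
  w <- kernel_weights(cells, g$x, g$y, bandwidth_um)
  dens <- rowSums(w) * grid_um^2 / (2 * pi * bandwidth_um^2)
  new_spatial_map(matrix(dens, length(g$y), length(g$x)),
                  g$x, g$y, "density", bandwidth_um, grid_um)
}

#' Kernel-smoothed map of a per-cell field
#'
#' Nadaraya-Watson kernel-weighted local mean of a cell field (unweighted
#' variant), or the local mean multiplied by local density
#' (density-weighted expression map). Grid cells whose kernel mass falls
#' below `mass_floor` cells are masked as no-data, so contours are never
#' extrapolated into cell-free space.
#'
#' @param cells cell table.
#' @param field one of `mrna_corr`, `protein_corr`, `quotient`.
#' @param grid_um,bandwidth_um grid and kernel scales (micrometres).
#' @param weighted_by_density multiply the local mean by local density.
#' @param bounds optional map bounds.
#' @param mass_floor kernel mass (cells per grid cell) below which the map
#'   is masked.
#' @return A `spatial_map`.
#' @export
value_map <- function(cells, field = c("quotient", "mrna_corr", "protein_corr"),
                      grid_um = 50, bandwidth_um = 150,
                      weighted_by_density = FALSE, bounds = NULL,
                      mass_floor = 1e-3) {
  field <- match.arg(field)
  if (!field %in% names(cells)) {
    abort(sprintf("unknown field '%s'", field),
          class = "mastmap_validation_error")
  }
  if (nrow(cells) == 0) {
    abort("value map needs at least one cell",
          class = "mastmap_degenerate_error")
  }
  g <- map_grid(cells, grid_um, bounds)
  w <- kernel_weights(cells, g$x, g$y, bandwidth_um)
  wsum <- rowSums(w)
  local_mean <- as.numeric(w %*% cells[[field]]) / wsum
  mass <- wsum * grid_um^2 / (2 * pi * bandwidth_um^2)
  local_mean[mass < mass_floor] <- NA_real_
  vals <- if (weighted_by_density) local_mean * mass else local_mean
  new_spatial_map(matrix(vals, length(g$y), length(g$x)),
                  g$x, g$y,
                  if (weighted_by_density) "density_weighted_expression"
                  else "mean_expression",
                  bandwidth_um, grid_um, field = field)
}

#' Compare a per-cell field between two spatial ROIs
#'
#' Two-sided Mann-Whitney test on the per-cell field values of cells whose
#' centroids fall inside each ROI polygon (pre-determined spatial regions of
#' interest on the section).
#'
#' @param cells cell table.
#' @param roi_a,roi_b ROI polygons (x, y matrices in micrometres).
#' @param field per-cell column to compare (default `quotient`).
#' @return A `mast_test` (see [mann_whitney()]) with ROI cell counts.
#' @export
compare_rois <- function(cells, roi_a, roi_b, field = "quotient") {
  if (!field %in% names(cells)) {
    abort(sprintf("unknown field '%s'", field),
          class = "mastmap_validation_error")
  }
  in_a <- point_in_polygon(cells$x_um, cells$y_um, roi_a)
  in_b <- point_in_polygon(cells$x_um, cells$y_um, roi_b)
  if (sum(in_a) < 5 || sum(in_b) < 5) {
    abort(sprintf("each ROI needs >= 5 cells (found %d and %d)",
                  sum(in_a), sum(in_b)),
          class = "mastmap_insufficient_data_error")
  }
  mann_whitney(cells[[field]][in_a], cells[[field]][in_b])
}
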