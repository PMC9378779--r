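# Tryptase-mask mast-cell segmentation: threshold -> connected components ->
# size filtration. No watershed splitting: merges are handled by the
# max-area filter, mirroring a pure threshold + size-filter protocol.

#' Threshold the tryptase channel into a mast-cell mask
#'
#' A pixel is masked iff its tryptase intensity is at or above the
#' threshold. The threshold is either the locked fixed value from the config
#' (default, one number across every section of a study run) or Otsu's
#' threshold on the section's tryptase histogram.
#'
#' @param image a [multiplex_image()].
#' @param config a [study_config()].
#' @return Logical matrix with attributes `threshold`, `pixel_size_um`.
#' @export
tryptase_mask <- function(image, config = study_config()) {
  stopifnot(inherits(image, "multiplex_image"))
  ch <- image$channels$tryptase
  thr <- if (config$tryptase_threshold_method == "fixed") {
    config$tryptase_threshold_value
  } else {
    rng <- range(ch)
    if (diff(rng) == 0) {
      abort("constant-intensity tryptase channel: Otsu threshold is degenerate",
            class = "mastmap_degenerate_error")
    }
    # Otsu on the normalised histogram, mapped back to intensity units
    EBImage::otsu(EBImage::Image((ch - rng[1]) / diff(rng)),
                  range = c(0, 1), levels = 256) * diff(rng) + rng[1]
  }
  inform(sprintf("tryptase threshold (%s): %.6g AU",
                 config$tryptase_threshold_method, thr))
  mask <- ch >= thr
  attr(mask, "threshold") <- thr
  attr(mask, "pixel_size_um") <- image$pixel_size_um
  mask
}

#' Label 8-connected components of a binary mask as cell ROIs
#'
#' Components use 8-connectivity (the blob-detection convention). ROI ids
#' are assigned in raster order of each component's first pixel
#' (left-to-right, top-to-bottom). Centroids are unweighted pixel centroids
#' in micrometres; `mean_tryptase` is the raw mean of the tryptase channel
#' over the ROI pixels.
#'
#' @param mask logical matrix (e.g. from [tryptase_mask()]).
#' @param image the [multiplex_image()] the mask came from.
#' @return Tibble with columns `id`, `x_um`, `y_um`, `area_um2`,
#'   `mean_tryptase`; attributes `label_image` (integer matrix, 0 =
#'   background, values = `id`) and `pixel_size_um`.
#' @export
label_components <- function(mask, image) {
  stopifnot(inherits(image, "multiplex_image"))
  px <- image$pixel_size_um
  H <- nrow(mask); W <- ncol(mask)
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), H, W))
  lab <- matrix(as.integer(lab), H, W)
  nlab <- max(lab)
  if (nlab > 0) {
    # EBImage::bwlabel is 4-connected; union labels across diagonal contacts
    parent <- seq_len(nlab)
    find <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    add_edges <- function(a, b) {
      sel <- which(a > 0L & b > 0L & a != b)
      for (s in sel) {
        ra <- find(a[s]); rb <- find(b[s])
        if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
      }
    }
    add_edges(lab[-H, -W], lab[-1, -1]) # down-right diagonal
    add_edges(lab[-H, -1], lab[-1, -W]) # down-left diagonal
    root <- vapply(seq_len(nlab), find, integer(1))
    lab[lab > 0L] <- root[lab[lab > 0L]]

    # renumber components in raster order of their first pixel
    idx <- which(lab > 0L)
    l <- lab[idx]
    r <- ((idx - 1L) %% H) + 1L
    c <- ((idx - 1L) %/% H) + 1L
    raster <- (r - 1L) * W + c
    first_px <- vapply(split(raster, l), min, numeric(1))
    old_ids <- as.integer(names(first_px))
    new_of <- integer(nlab)
    new_of[old_ids[order(first_px)]] <- seq_along(old_ids)
    lab[idx] <- new_of[l]
    l <- lab[idx]

    n_px <- tabulate(l)
    x_um <- (c - 0.5) * px
    y_um <- (r - 0.5) * px
    tr <- image$channels$tryptase[idx]
    rois <- tibble::tibble(
      id = seq_along(n_px),
      x_um = as.numeric(rowsum(x_um, l)) / n_px,
      y_um = as.numeric(rowsum(y_um, l)) / n_px,
      area_um2 = n_px * px^2,
      mean_tryptase = as.numeric(rowsum(tr, l)) / n_px
    )
  } else {
    rois <- tibble::tibble(id = integer(0), x_um = numeric(0),
                           y_um = numeric(0), area_um2 = numeric(0),
                           mean_tryptase = numeric(0))
  }
  attr(rois, "label_image") <- lab
  attr(rois, "pixel_size_um") <- px
  rois
}

#' Filter cell ROIs by area
#'
#' Keeps ROIs whose area lies inside the inclusive `[min, max]` window;
#' order is preserved and removal counts are reported.
#'
#' @param rois ROI tibble from [label_components()].
#' @param min_area_um2,max_area_um2 inclusive bounds in square micrometres.
#' @return Filtered ROI tibble (attributes preserved, plus
#'   `n_removed_small` / `n_removed_large`).
#' @export
filter_by_size <- function(rois, min_area_um2, max_area_um2) {
  keep <- rois$area_um2 >= min_area_um2 & rois$area_um2 <= max_area_um2
  n_small <- sum(rois$area_um2 < min_area_um2)
  n_large <- sum(rois$area_um2 > max_area_um2)
  inform(sprintf("size filter [%g, %g] um2: removed %d small, %d large of %d ROIs",
                 min_area_um2, max_area_um2, n_small, n_large, nrow(rois)))
  out <- rois[keep, ]
  attr(out, "label_image") <- attr(rois, "label_image")
  attr(out, "pixel_size_um") <- attr(rois, "pixel_size_um")
  attr(out, "n_removed_small") <- n_small
  attr(out, "n_removed_large") <- n_large
  out
}

#' Segment mast cells from the tryptase channel
#'
#' Composition of [tryptase_mask()], [label_components()] and
#' [filter_by_size()]; deterministic.
#'
#' @param image a [multiplex_image()].
#' @param config a [study_config()].
#' @return Filtered ROI tibble (see [label_components()]).
#' @export
segment_mast_cells <- function(image, config = study_config()) {
  mask <- tryptase_mask(image, config)
  rois <- label_components(mask, image)
  rois <- filter_by_size(rois, config$min_cell_area_um2, config$max_cell_area_um2)
  attr(rois, "threshold") <- attr(mask, "threshold")
  rois
}
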