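# Per-cell dual-channel quantification: mask superposition, background
# subtraction, quotients, locked gates, compartment assignment, patient
# summaries.

#' Tissue mask and analysed tissue area
#'
#' Tissue is defined on the nuclei channel: pixels whose Gaussian-smoothed
#' intensity reaches the config threshold, morphologically closed to fill
#' small gaps. The analysed tissue area (mm^2) normalises densities and
#' chromogen fractions.
#'
#' @param image a [multiplex_image()].
#' @param config a [study_config()].
#' @return Logical matrix with attribute `area_mm2`.
#' @export
tissue_mask <- function(image, config = study_config()) {
  stopifnot(inherits(image, "multiplex_image"))
  nuc <- image$channels$nuclei
  sm <- separable_gaussian_blur(nuc, sigma = 2, half = 4)
  mask <- sm >= config$tissue_threshold
  if (any(mask)) {
    mask <- as.matrix(EBImage::closing(
      EBImage::Image(mask * 1), EBImage::makeBrush(5, "disc"))) > 0
  }
  if (!any(mask)) {
    abort("no tissue found above the nuclei threshold",
          class = "mastmap_degenerate_error")
  }
  attr(mask, "area_mm2") <- sum(mask) * image$pixel_size_um^2 / 1e6
  mask
}

#' Estimate tissue background fluorescence for one channel
#'
#' Background is the median intensity over tissue pixels that do not belong
#' to any segmented cell ROI dilated by 2 pixels. Estimated per section and
#' per channel.
#'
#' @param image a [multiplex_image()].
#' @param channel `"mrna"` or `"protein"`.
#' @param rois ROI tibble carrying a `label_image` attribute
#'   ([label_components()] output; all labelled pixels are excluded, whether
#'   or not they survived size filtration).
#' @param tissue logical tissue mask from [tissue_mask()].
#' @return Scalar background level (AU); 0 with a warning when no eligible
#'   pixel exists.
#' @export
estimate_background <- function(image, channel = c("mrna", "protein"),
                                rois, tissue) {
  channel <- match.arg(channel)
  lab <- attr(rois, "label_image")
  if (is.null(lab)) abort("rois must carry a label_image attribute")
  cellmask <- lab > 0L
  if (any(cellmask)) {
    cellmask <- as.matrix(EBImage::dilate(
      EBImage::Image(cellmask * 1), EBImage::makeBrush(5, "disc"))) > 0
  }
  eligible <- tissue & !cellmask
  if (!any(eligible)) {
    warn(sprintf("no cell-free tissue pixels for '%s' background; using 0", channel))
    return(0)
  }
  stats::median(image$channels[[channel]][eligible])
}

#' Measure per-cell raw and background-corrected intensities
#'
#' Superimposes each ROI's exact pixel set on the mRNA and protein channels;
#' raw values are pixel means over the ROI, corrected values subtract the
#' per-section channel background and floor at zero (negative fluorescence
#' is unphysical; the floored count is reported).
#'
#' @param image a [multiplex_image()].
#' @param rois filtered ROI tibble (with `label_image` attribute).
#' @param backgrounds named numeric vector `c(mrna = ..., protein = ...)`.
#' @param patient_id,section_id identifiers stamped on the rows.
#' @return A cell-table tibble (quotient, gates and compartment columns
#'   initialised; fill them with [compute_quotient()], [gate_high()] and
#'   [assign_compartments()]).
#' @export
measure_cells <- function(image, rois, backgrounds,
                          patient_id = "patient", section_id = NULL) {
  stopifnot(inherits(image, "multiplex_image"))
  if (!all(c("mrna", "protein") %in% names(backgrounds))) {
    abort("backgrounds must be named with 'mrna' and 'protein'")
  }
  section_id <- section_id %||% image$source_id
  lab <- attr(rois, "label_image")
  if (is.null(lab)) abort("rois must carry a label_image attribute")
  if (nrow(rois) == 0) return(empty_cell_table())
  if (any(dim(lab) != dim(image$channels$mrna))) {
    abort("ROI label image does not match image dimensions",
          class = "mastmap_indexing_error")
  }
  idx <- which(lab > 0L)
  l <- lab[idx]
  sel <- l %in% rois$id
  idx <- idx[sel]; l <- l[sel]
  n_px <- as.numeric(table(factor(l, levels = rois$id)))
  mr <- rowsum(image$channels$mrna[idx], factor(l, levels = rois$id))
  pr <- rowsum(image$channels$protein[idx], factor(l, levels = rois$id))
  mrna_raw <- as.numeric(mr) / n_px
  protein_raw <- as.numeric(pr) / n_px
  mrna_corr <- pmax(0, mrna_raw - backgrounds[["mrna"]])
  protein_corr <- pmax(0, protein_raw - backgrounds[["protein"]])
  n_floored <- sum(mrna_raw < backgrounds[["mrna"]]) +
    sum(protein_raw < backgrounds[["protein"]])
  if (n_floored > 0) {
    inform(sprintf("%d corrected intensities floored at 0", n_floored))
  }
  tibble::tibble(
    cell_id = rois$id,
    patient_id = patient_id,
    section_id = section_id,
    x_um = rois$x_um, y_um = rois$y_um, area_um2 = rois$area_um2,
    mean_tryptase = rois$mean_tryptase,
    mrna_raw = mrna_raw, protein_raw = protein_raw,
    mrna_corr = mrna_corr, protein_corr = protein_corr,
    quotient = NA_real_, mrna_high = NA, protein_high = NA,
    compartment = NA_character_
  )
}

#' Compute the per-cell mRNA/protein quotient
#'
#' `quotient = mrna_corr / (protein_corr + epsilon)`. The epsilon
#' regularisation keeps protein-negative cells (which demonstrably exist) in
#' the analysis with a finite quotient.
#'
#' @param cells cell table with corrected intensities.
#' @param epsilon regularisation (AU), > 0; default from [study_config()].
#' @return The cell table with `quotient` filled.
#' @export
compute_quotient <- function(cells, epsilon = study_config()$quotient_epsilon) {
  if (!is.numeric(epsilon) || length(epsilon) != 1 || epsilon <= 0) {
    abort("epsilon must be a single number > 0",
          class = "mastmap_validation_error")
  }
  dplyr::mutate(cells, quotient = .data$mrna_corr / (.data$protein_corr + epsilon))
}

#' Gate cells as mRNA-high / protein-high
#'
#' Locked-threshold gating: a cell is high iff its corrected intensity is
#' strictly above the study-wide gate; a value exactly at the gate is not
#' high. The same thresholds apply to every section of a run.
#'
#' @param cells cell table with corrected intensities.
#' @param config a [study_config()] supplying `mrna_high_threshold` and
#'   `protein_high_threshold`.
#' @return The cell table with `mrna_high` and `protein_high` filled.
#' @export
gate_high <- function(cells, config = study_config()) {
  dplyr::mutate(cells,
                mrna_high = .data$mrna_corr > config$mrna_high_threshold,
                protein_high = .data$protein_corr > config$protein_high_threshold)
}

#' Assign cells to anatomical compartments
#'
#' A cell belongs to the region containing its centroid; nested regions
#' resolve innermost-first (epithelium before subepithelium before
#' parenchyma), ties by annotation order; centroids in no region become
#' `"unassigned"`.
#'
#' @param cells cell table.
#' @param annotation a [compartment_annotation()].
#' @return The cell table with `compartment` filled.
#' @export
assign_compartments <- function(cells, annotation) {
  stopifnot(inherits(annotation, "compartment_annotation"))
  if (nrow(cells) == 0) return(cells)
  ri <- assign_region_index(cells$x_um, cells$y_um, annotation, "innermost")
  lab <- ifelse(is.na(ri), "unassigned", annotation$label[ri])
  dplyr::mutate(cells, compartment = lab)
}

#' Full single-section quantification
#'
#' Convenience composition: segmentation, tissue mask, per-channel
#' background estimation, measurement, quotient, gating and compartment
#' assignment.
#'
#' @param image a [multiplex_image()].
#' @param annotation a [compartment_annotation()].
#' @param config a [study_config()].
#' @param patient_id,section_id identifiers.
#' @return A complete cell table.
#' @export
quantify_section <- function(image, annotation, config = study_config(),
                             patient_id = "patient", section_id = NULL) {
  rois <- segment_mast_cells(image, config)
  tis <- tissue_mask(image, config)
  bg <- c(mrna = estimate_background(image, "mrna", rois, tis),
          protein = estimate_background(image, "protein", rois, tis))
  cells <- measure_cells(image, rois, bg, patient_id, section_id)
  cells <- compute_quotient(cells, config$quotient_epsilon)
  cells <- gate_high(cells, config)
  cells <- assign_compartments(cells, annotation)
  attr(cells, "backgrounds") <- bg
  attr(cells, "tissue_area_mm2") <- attr(tis, "area_mm2")
  cells
}

#' Per-patient per-compartment summary
#'
#' Aggregates one patient's cells: arithmetic means of corrected mRNA,
#' protein and quotient; mast-cell density per mm^2 of compartment area;
#' fractions of gated high cells. Compartments with no cells report missing
#' means and density 0.
#'
#' @param cells cell table for one patient (compartments assigned).
#' @param annotation the section's [compartment_annotation()] (compartment
#'   areas are the nesting-aware effective areas).
#' @param group group label copied onto the summary rows.
#' @return Tibble with one row per anatomical compartment.
#' @export
summarize_patient <- function(cells, annotation, group = NA_character_) {
  stopifnot(inherits(annotation, "compartment_annotation"))
  areas <- annotation_areas(annotation, effective = TRUE)
  areas <- dplyr::summarise(dplyr::group_by(areas, .data$label),
                            area_um2 = sum(.data$area_um2), .groups = "drop")
  areas <- areas[areas$label != "excluded", ]
  if (any(areas$area_um2 <= 0)) {
    abort("compartment with zero area", class = "mastmap_validation_error")
  }
  patient_id <- if (nrow(cells) > 0) cells$patient_id[1] else NA_character_
  out <- lapply(seq_len(nrow(areas)), function(i) {
    comp <- areas$label[i]
    cc <- cells[!is.na(cells$compartment) & cells$compartment == comp, ]
    n <- nrow(cc)
    tibble::tibble(
      patient_id = patient_id, group = group, compartment = comp,
      n_cells = n,
      mean_mrna_corr = if (n) mean(cc$mrna_corr) else NA_real_,
      mean_protein_corr = if (n) mean(cc$protein_corr) else NA_real_,
      mean_quotient = if (n) mean(cc$quotient) else NA_real_,
      density_cells_per_mm2 = n / (areas$area_um2[i] / 1e6),
      frac_mrna_high = if (n) mean(cc$mrna_high) else NA_real_,
      frac_protein_high = if (n) mean(cc$protein_high) else NA_real_,
      compartment_area_mm2 = areas$area_um2[i] / 1e6
    )
  })
  dplyr::bind_rows(out)
}
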