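#' Study configuration
#'
#' A single locked parameter set governing a whole study run, mirroring the
#' locked-exposure / locked-threshold philosophy of quantitative slide
#' cytometry: one threshold per quantity, fixed across every section.
#'
#' @param tryptase_threshold_method `"fixed"` (default) or `"otsu"`; how the
#'   mast-cell mask threshold on the tryptase channel is chosen.
#' @param tryptase_threshold_value intensity (AU) used when the method is
#'   `"fixed"`.
#' @param min_cell_area_um2,max_cell_area_um2 inclusive ROI size-filtration
#'   window in square micrometres.
#' @param quotient_epsilon regularisation added to the protein denominator of
#'   the mRNA/protein quotient (AU), keeping protein-negative cells finite.
#' @param mrna_high_threshold,protein_high_threshold locked gates on
#'   background-corrected intensity (AU); a cell is "high" strictly above the
#'   gate.
#' @param tissue_threshold smoothed nuclei-channel intensity above which a
#'   pixel counts as tissue.
#' @param gene_min,gene_max,umi_min,umi_max,mito_max_frac scRNA-seq cell QC
#'   window (inclusive bounds).
#' @param cpa3_split_threshold log-normalised CPA3 value at or below which a
#'   mast cell is classed CPA3-low.
#' @param mito_prefix gene-name prefix (case-insensitive) flagging
#'   mitochondrial genes.
#' @param scrna_scale per-cell total after count scaling, before log1p.
#' @param mast_markers marker genes used for mast-cell selection.
#' @param mast_min_positive minimum number of positive markers for selection.
#' @param od_threshold chromogen optical-density threshold for immunoreactive
#'   area.
#' @param dunn_adjust p-adjustment for Dunn's post-hoc test (`"bonferroni"`,
#'   the Prism convention, by default).
#' @param pixel_size_um default micrometres per pixel edge when an image file
#'   carries no trusted metadata.
#' @param bit_depth nominal scanner bit depth (informational).
#' @param rng_seed default seed for stochastic helpers.
#' @return An object of class `study_config` (a validated named list).
#' @export
study_config <- function(tryptase_threshold_method = c("fixed", "otsu"),
                         tryptase_threshold_value = 300,
                         min_cell_area_um2 = 20,
                         max_cell_area_um2 = 700,
                         quotient_epsilon = 1,
                         mrna_high_threshold = 300,
                         protein_high_threshold = 300,
                         tissue_threshold = 50,
                         gene_min = 1000, gene_max = 75000,
                         umi_min = 1000, umi_max = 75000,
                         mito_max_frac = 0.20,
                         cpa3_split_threshold = 1.5,
                         mito_prefix = "MT-",
                         scrna_scale = 10000,
                         mast_markers = c("TPSAB1", "TPSB2", "MS4A2", "CPA3"),
                         mast_min_positive = 2,
                         od_threshold = 0.15,
                         dunn_adjust = "bonferroni",
                         pixel_size_um = 0.5,
                         bit_depth = 16,
                         rng_seed = 1) {
  cfg <- list(
    tryptase_threshold_method = match.arg(tryptase_threshold_method),
    tryptase_threshold_value = tryptase_threshold_value,
    min_cell_area_um2 = min_cell_area_um2,
    max_cell_area_um2 = max_cell_area_um2,
    quotient_epsilon = quotient_epsilon,
    mrna_high_threshold = mrna_high_threshold,
    protein_high_threshold = protein_high_threshold,
    tissue_threshold = tissue_threshold,
    gene_min = gene_min, gene_max = gene_max,
    umi_min = umi_min, umi_max = umi_max,
    mito_max_frac = mito_max_frac,
    cpa3_split_threshold = cpa3_split_threshold,
    mito_prefix = mito_prefix,
    scrna_scale = scrna_scale,
    mast_markers = mast_markers,
    mast_min_positive = mast_min_positive,
    od_threshold = od_threshold,
    dunn_adjust = dunn_adjust,
    pixel_size_um = pixel_size_um,
    bit_depth = bit_depth,
    rng_seed = rng_seed
  )
  validate_study_config(cfg)
}

validate_study_config <- function(cfg) {
  num_fields <- c("tryptase_threshold_value", "min_cell_area_um2",
                  "max_cell_area_um2", "quotient_epsilon",
                  "mrna_high_threshold", "protein_high_threshold",
                  "tissue_threshold", "gene_min", "gene_max", "umi_min",
                  "umi_max", "mito_max_frac", "cpa3_split_threshold",
                  "od_threshold", "pixel_size_um")
  for (f in num_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0) {
      abort(sprintf("config field '%s' must be a single finite number >= 0", f))
    }
  }
  if (cfg$min_cell_area_um2 >= cfg$max_cell_area_um2) {
    abort("min_cell_area_um2 must be smaller than max_cell_area_um2")
  }
  if (cfg$mito_max_frac > 1) {
    abort("mito_max_frac must lie in [0, 1]")
  }
  if (cfg$pixel_size_um <= 0) abort("pixel_size_um must be > 0")
  if (!cfg$tryptase_threshold_method %in% c("fixed", "otsu")) {
    abort("tryptase_threshold_method must be 'fixed' or 'otsu'")
  }
  structure(cfg, class = "study_config")
}

#' Load a study configuration from YAML or JSON
#'
#' Absent keys take the package defaults of [study_config()]; the merged
#' configuration is validated. File type is decided by extension (`.json`
#' parses as JSON, anything else as YAML).
#'
#' @param path path to a YAML or JSON configuration file.
#' @return A `study_config` object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(vals)) vals <- list()
  if (!is.list(vals)) abort("config file must contain a mapping of keys to values")
  defaults <- study_config()
  unknown <- setdiff(names(vals), names(defaults))
  if (length(unknown)) {
    warn(sprintf("ignoring unknown config keys: %s", paste(unknown, collapse = ", ")))
    vals <- vals[setdiff(names(vals), unknown)]
  }
  validate_study_config(modifyList(unclass(defaults), vals))
}

#' @export
print.study_config <- function(x, ...) {
  cat("<study_config>\n")
  for (f in names(x)) {
    cat(sprintf("  %-26s %s\n", f, paste(format(x[[f]]), collapse = ", ")))
  }
  invisible(x)
}
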