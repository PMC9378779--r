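# The CellTable: one record per segmented mast cell.

CELL_TABLE_COLUMNS <- c(
  "cell_id", "patient_id", "section_id", "x_um", "y_um", "area_um2",
  "mean_tryptase", "mrna_raw", "protein_raw", "mrna_corr", "protein_corr",
  "quotient", "mrna_high", "protein_high", "compartment"
)

# Coerce/verify a cell table. Columns beyond the fixed set are tolerated in
# memory but only the fixed header is persisted.
validate_cell_table <- function(cells) {
  missing <- setdiff(CELL_TABLE_COLUMNS, names(cells))
  if (length(missing)) {
    abort(sprintf("cell table is missing column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "mastmap_format_error")
  }
  num_ok <- c("mrna_corr", "protein_corr", "quotient")
  for (f in num_ok) {
    v <- cells[[f]]
    if (any(!is.na(v) & v < 0)) abort(sprintf("column '%s' must be >= 0", f))
  }
  bad <- setdiff(unique(cells$compartment),
                 c(compartment_vocab(), "unassigned", NA))
  if (length(bad)) {
    abort(sprintf("unknown compartment value(s): %s", paste(bad, collapse = ", ")))
  }
  cells
}

#' Save a cell table to CSV
#'
#' Writes the fixed 15-column header; numeric fields survive a save/load
#' round trip to full double precision.
#'
#' @param cells a cell table (tibble with the columns produced by
#'   [measure_cells()] and friends).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
save_cell_table <- function(cells, path) {
  if (nrow(cells) > 0) validate_cell_table(cells)
  out <- if (nrow(cells) == 0) {
    empty_cell_table()
  } else {
    cells[, CELL_TABLE_COLUMNS]
  }
  readr::write_csv(out, path)
  invisible(path)
}

#' Load a cell table from CSV
#'
#' @param path path to a CSV written by [save_cell_table()].
#' @return A validated cell-table tibble.
#' @export
load_cell_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("cell table not found: %s", path))
  header <- strsplit(readLines(path, n = 1), ",")[[1]]
  missing <- setdiff(CELL_TABLE_COLUMNS, header)
  if (length(missing)) {
    abort(sprintf("malformed cell table header; missing: %s",
                  paste(missing, collapse = ", ")),
          class = "mastmap_format_error")
  }
  cells <- readr::read_csv(path, col_types = readr::cols(
    cell_id = readr::col_integer(),
    patient_id = readr::col_character(),
    section_id = readr::col_character(),
    mrna_high = readr::col_logical(),
    protein_high = readr::col_logical(),
    compartment = readr::col_character(),
    .default = readr::col_double()
  ))
  if (nrow(cells) > 0) validate_cell_table(cells)
  cells[, CELL_TABLE_COLUMNS]
}

empty_cell_table <- function() {
  tibble::tibble(
    cell_id = integer(0), patient_id = character(0), section_id = character(0),
    x_um = numeric(0), y_um = numeric(0), area_um2 = numeric(0),
    mean_tryptase = numeric(0), mrna_raw = numeric(0), protein_raw = numeric(0),
    mrna_corr = numeric(0), protein_corr = numeric(0), quotient = numeric(0),
    mrna_high = logical(0), protein_high = logical(0), compartment = character(0)
  )
}
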