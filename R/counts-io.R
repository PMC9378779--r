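# Sparse gene x cell UMI count matrices (Matrix Market + TSV sidecars).

#' Construct a count matrix
#'
#' @param counts genes x cells matrix of non-negative integer UMI counts
#'   (dense or any Matrix sparse class; stored as `dgCMatrix`).
#' @param gene_names,cell_ids character vectors matching the matrix
#'   dimensions.
#' @param mito_prefix gene-name prefix (case-insensitive) marking
#'   mitochondrial genes.
#' @return An object of class `count_matrix`: a list with `counts`
#'   (dgCMatrix, dimnames set) and `mito` (logical per gene).
#' @export
count_matrix <- function(counts, gene_names = rownames(counts),
                         cell_ids = colnames(counts), mito_prefix = "MT-") {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  if (is.null(gene_names) || is.null(cell_ids)) {
    abort("gene_names and cell_ids are required")
  }
  if (length(gene_names) != nrow(counts) || length(cell_ids) != ncol(counts)) {
    abort("dimension mismatch between counts and gene/cell name lists",
          class = "mastmap_format_error")
  }
  x <- counts@x
  if (any(x < 0) || any(x != round(x))) {
    abort("counts must be non-negative integers")
  }
  dimnames(counts) <- list(gene_names, cell_ids)
  mito <- startsWith(toupper(gene_names), toupper(mito_prefix))
  structure(list(counts = counts, mito = setNames(mito, gene_names)),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d genes x %d cells, %d mito genes, %.0f UMIs\n",
              nrow(x$counts), ncol(x$counts), sum(x$mito), sum(x$counts)))
  invisible(x)
}

#' Load a count matrix from a 10x-style directory
#'
#' Expects `matrix.mtx` (genes x cells Matrix Market), `features.tsv` (gene
#' names; for two-or-more-column 10x files the second column is taken as the
#' name) and `barcodes.tsv`.
#'
#' @param dir directory containing the three files.
#' @param mito_prefix prefix rule for mitochondrial gene flags
#'   (case-insensitive; default `"MT-"`).
#' @return A [count_matrix()].
#' @export
load_counts <- function(dir, mito_prefix = "MT-") {
  paths <- file.path(dir, c("matrix.mtx", "features.tsv", "barcodes.tsv"))
  if (!all(file.exists(paths))) {
    abort(sprintf("expected matrix.mtx, features.tsv, barcodes.tsv under %s", dir),
          class = "mastmap_format_error")
  }
  m <- Matrix::readMM(paths[1])
  feats <- utils::read.delim(paths[2], header = FALSE, stringsAsFactors = FALSE)
  genes <- if (ncol(feats) >= 2) feats[[2]] else feats[[1]]
  cells <- utils::read.delim(paths[3], header = FALSE,
                             stringsAsFactors = FALSE)[[1]]
  if (nrow(m) != length(genes) || ncol(m) != length(cells)) {
    abort(sprintf(
      "matrix is %d x %d but sidecars list %d genes and %d barcodes",
      nrow(m), ncol(m), length(genes), length(cells)),
      class = "mastmap_format_error")
  }
  count_matrix(m, genes, cells, mito_prefix = mito_prefix)
}

#' Save a count matrix in Matrix Market + TSV form
#'
#' @param cm a [count_matrix()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_counts <- function(cm, dir) {
  stopifnot(inherits(cm, "count_matrix"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(cm$counts, file.path(dir, "matrix.mtx"))
  writeLines(rownames(cm$counts), file.path(dir, "features.tsv"))
  writeLines(colnames(cm$counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}
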