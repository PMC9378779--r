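# scRNA-seq workflow: cell QC, log-normalisation, marker-based mast-cell
# selection, CPA3 high/low partition, and marker ranking.

#' Per-cell QC metrics
#'
#' @param cm a [count_matrix()].
#' @param config a [study_config()] supplying the QC window (genes and UMIs
#'   each in `[1000, 75000]`, mitochondrial fraction in `[0, 0.20]`,
#'   inclusive).
#' @return Tibble: `cell_id`, `n_genes`, `total_umi`, `mito_fraction`,
#'   `passes`.
#' @export
qc_metrics <- function(cm, config = study_config()) {
  stopifnot(inherits(cm, "count_matrix"))
  n_genes <- Matrix::colSums(cm$counts > 0)
  total_umi <- Matrix::colSums(cm$counts)
  mito_umi <- if (any(cm$mito)) {
    Matrix::colSums(cm$counts[cm$mito, , drop = FALSE])
  } else rep(0, ncol(cm$counts))
  mito_fraction <- ifelse(total_umi > 0, mito_umi / total_umi, 0)
  passes <- n_genes >= config$gene_min & n_genes <= config$gene_max &
    total_umi >= config$umi_min & total_umi <= config$umi_max &
    mito_fraction >= 0 & mito_fraction <= config$mito_max_frac
  tibble::tibble(cell_id = colnames(cm$counts),
                 n_genes = as.integer(unname(n_genes)),
                 total_umi = as.numeric(unname(total_umi)),
                 mito_fraction = as.numeric(unname(mito_fraction)),
                 passes = unname(passes))
}

#' Filter cells on the QC window
#'
#' Keeps cells whose detected-gene count, UMI total and mitochondrial
#' fraction all lie inside the inclusive QC bounds; metrics are returned
#' for every input cell.
#'
#' @inheritParams qc_metrics
#' @return List with `counts` (filtered [count_matrix()]) and `metrics`
#'   (QC tibble over all input cells).
#' @export
qc_filter <- function(cm, config = study_config()) {
  met <- qc_metrics(cm, config)
  if (!any(met$passes)) {
    warn("no cells pass the QC window; returning an empty matrix")
  }
  kept <- cm$counts[, met$passes, drop = FALSE]
  out <- structure(list(counts = kept, mito = cm$mito), class = "count_matrix")
  list(counts = out, metrics = met)
}

#' Log-normalise a count matrix
#'
#' Scales every cell to `scale` total counts, then applies `log(1 + x)`.
#' Zero-total cells are excluded with a warning.
#'
#' @param cm a [count_matrix()] (typically QC-filtered).
#' @param scale per-cell total after scaling (default 10,000).
#' @return A genes x cells `dgCMatrix` of log-normalised values with
#'   attribute `scale`.
#' @export
normalize_log <- function(cm, scale = study_config()$scrna_scale) {
  stopifnot(inherits(cm, "count_matrix"))
  tot <- Matrix::colSums(cm$counts)
  if (any(tot == 0)) {
    warn(sprintf("excluding %d zero-total cell(s) from normalisation",
                 sum(tot == 0)))
  }
  m <- cm$counts[, tot > 0, drop = FALSE]
  tot <- tot[tot > 0]
  norm <- m %*% Matrix::Diagonal(x = scale / tot)
  norm@x <- log1p(norm@x)
  norm <- methods::as(norm, "CsparseMatrix")
  dimnames(norm) <- list(rownames(m), colnames(m))
  attr(norm, "scale") <- scale
  norm
}

#' Select mast cells by marker expression
#'
#' A cell is a mast cell when at least `min_positive` of the marker genes
#' (TPSB2, TPSAB1, MS4A2, CPA3 by default) have normalised expression
#' strictly above zero.
#'
#' @param expr log-normalised genes x cells matrix from [normalize_log()].
#' @param markers marker gene names; all must be present in the panel.
#' @param min_positive minimum number of positive markers (default 2).
#' @return Tibble: `cell_id`, `n_markers_positive`, `is_mast`.
#' @export
select_mast_cells <- function(expr,
                              markers = study_config()$mast_markers,
                              min_positive = study_config()$mast_min_positive) {
  missing <- setdiff(markers, rownames(expr))
  if (length(missing)) {
    abort(sprintf("marker gene(s) absent from panel: %s",
                  paste(missing, collapse = ", ")),
          class = "mastmap_config_error")
  }
  pos <- unname(Matrix::colSums(expr[markers, , drop = FALSE] > 0))
  tibble::tibble(cell_id = colnames(expr),
                 n_markers_positive = as.integer(pos),
                 is_mast = pos >= min_positive)
}

#' Partition mast cells into CPA3-high and CPA3-low
#'
#' High iff normalised CPA3 is strictly above the threshold; a value exactly
#' at the threshold (default 1.5) is low.
#'
#' @param expr log-normalised genes x cells matrix.
#' @param cell_ids cells to classify (default: all columns).
#' @param threshold split threshold on normalised CPA3 (default 1.5).
#' @return Tibble: `cell_id`, `cpa3`, `cpa3_class` (`"high"`/`"low"`).
#' @export
split_cpa3 <- function(expr, cell_ids = colnames(expr),
                       threshold = study_config()$cpa3_split_threshold) {
  if (!"CPA3" %in% rownames(expr)) {
    abort("CPA3 absent from panel", class = "mastmap_config_error")
  }
  cell_ids <- intersect(cell_ids, colnames(expr))
  v <- as.numeric(expr["CPA3", cell_ids])
  tibble::tibble(cell_id = cell_ids, cpa3 = v,
                 cpa3_class = ifelse(v > threshold, "high", "low"))
}

#' Rank genes upregulated in CPA3-high versus CPA3-low mast cells
#'
#' Per gene: two-sided Wilcoxon rank-sum test (tie-corrected normal
#' approximation) of high versus low cells on normalised expression,
#' Benjamini-Hochberg adjusted q-values, effect = difference of class means.
#' Genes are ranked by effect, largest first.
#'
#' @param expr log-normalised genes x cells matrix.
#' @param labels tibble from [split_cpa3()] (columns `cell_id`,
#'   `cpa3_class`) or a named character vector of classes.
#' @param top_n rows to return (default 48); `Inf` for all genes.
#' @return Tibble: `gene`, `effect`, `mean_high`, `mean_low`, `p_value`,
#'   `q_value`, ordered for heatmap display.
#' @export
rank_markers <- function(expr, labels, top_n = 48) {
  if (is.data.frame(labels)) {
    labels <- setNames(labels$cpa3_class, labels$cell_id)
  }
  labels <- labels[intersect(names(labels), colnames(expr))]
  hi <- names(labels)[labels == "high"]
  lo <- names(labels)[labels == "low"]
  if (length(hi) < 3 || length(lo) < 3) {
    abort("need at least 3 cells in each CPA3 class",
          class = "mastmap_insufficient_data_error")
  }
  x <- as.matrix(expr[, c(hi, lo), drop = FALSE])
  n1 <- length(hi); n2 <- length(lo); n <- n1 + n2
  rk <- t(apply(x, 1, rank)) # average ranks for ties
  r1 <- rowSums(rk[, seq_len(n1), drop = FALSE])
  u <- r1 - n1 * (n1 + 1) / 2
  mu_u <- n1 * n2 / 2
  # tie correction per gene
  tie_term <- apply(x, 1, function(v) {
    t <- table(v)
    sum(t^3 - t)
  })
  sig2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  z <- ifelse(sig2 > 0, (u - mu_u) / sqrt(sig2), 0)
  p <- 2 * pnorm(-abs(z))
  p <- pmin(1, p)
  q <- p.adjust(p, "BH")
  mean_high <- unname(rowMeans(x[, seq_len(n1), drop = FALSE]))
  mean_low <- unname(rowMeans(x[, n1 + seq_len(n2), drop = FALSE]))
  out <- tibble::tibble(gene = rownames(x),
                        effect = mean_high - mean_low,
                        mean_high = mean_high, mean_low = mean_low,
                        p_value = unname(p), q_value = unname(q))
  out <- dplyr::arrange(out, dplyr::desc(.data$effect))
  head(out, top_n)
}

#' Full scRNA-seq mast-cell analysis
#'
#' QC filter, log-normalise, select mast cells, split on CPA3, rank
#' upregulated genes.
#'
#' @param cm a [count_matrix()].
#' @param config a [study_config()].
#' @param top_n genes to report from [rank_markers()].
#' @return List with `qc`, `mast`, `cpa3`, `markers` tibbles.
#' @export
analyze_scrna <- function(cm, config = study_config(), top_n = 48) {
  flt <- qc_filter(cm, config)
  expr <- normalize_log(flt$counts, config$scrna_scale)
  mast <- select_mast_cells(expr, config$mast_markers, config$mast_min_positive)
  ids <- mast$cell_id[mast$is_mast]
  cls <- split_cpa3(expr, ids, config$cpa3_split_threshold)
  mk <- if (sum(cls$cpa3_class == "high") >= 3 &&
            sum(cls$cpa3_class == "low") >= 3) {
    rank_markers(expr[, ids, drop = FALSE], cls, top_n)
  } else NULL
  list(qc = flt$metrics, mast = mast, cpa3 = cls, markers = mk)
}
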