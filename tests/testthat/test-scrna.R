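toy_counts <- function(m, genes = NULL, mito_prefix = "MT-") {
  genes <- genes %||% sprintf("G%03d", seq_len(nrow(m)))
  count_matrix(m, genes, sprintf("c%03d", seq_len(ncol(m))),
               mito_prefix = mito_prefix)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("QC boundaries are inclusive exactly as stated", {
  cfg <- study_config(gene_min = 3, gene_max = 10, umi_min = 5, umi_max = 100)
  # cell 1: 2 detected genes, under the floor      -> removed
  # cell 2: 3 genes and 5 UMIs, both at the floor  -> kept (inclusive)
  # cell 3: mito fraction exactly 0.20             -> kept (inclusive)
  # cell 4: mito fraction 0.21, all else in range  -> removed
  m <- cbind(c(3, 2, 0, 0), c(2, 2, 1, 0), c(4, 2, 2, 2), c(50, 20, 9, 21))
  cm <- toy_counts(m, c("A", "B", "C", "MT-1"))
  met <- qc_metrics(cm, cfg)
  expect_equal(met$passes, c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(met$mito_fraction[3], 0.2)
  expect_equal(met$mito_fraction[4], 0.21)
})

test_that("qc_filter equals the brute-force predicate on random toys", {
  cfg <- study_config(gene_min = 3, gene_max = 40, umi_min = 5, umi_max = 300)
  set.seed(13)
  for (rep in 1:30) {
    m <- matrix(rpois(30 * 12, 2), 30, 12)
    genes <- c(paste0("MT-", 1:3), sprintf("G%02d", 1:27))
    cm <- toy_counts(m, genes)
    flt <- suppressWarnings(qc_filter(cm, cfg))
    expect_identical(flt$metrics$passes, brute_force_qc(cm, cfg))
    expect_identical(colnames(flt$counts$counts),
                     flt$metrics$cell_id[flt$metrics$passes])
  }
})

test_that("log-normalisation: arithmetic, rank preservation, zero cells", {
  m <- cbind(c(5, 0, 0), c(2, 3, 5), c(0, 0, 0))
  cm <- toy_counts(m)
  expect_warning(expr <- normalize_log(cm, scale = 10000))
  expect_equal(ncol(expr), 2)                       # zero-total cell dropped
  expect_equal(expr["G001", 1], log(1 + 10000))     # single-gene cell
  expect_equal(expr["G002", 1], 0)                  # count 0 -> 0
  # within-cell rank order preserved
  set.seed(14)
  m2 <- matrix(rpois(40 * 6, 4), 40, 6)
  e2 <- normalize_log(toy_counts(m2))
  for (j in 1:6) {
    expect_equal(rank(as.numeric(e2[, j])), rank(m2[, j]))
  }
  # per-cell pre-log totals equal the scale factor
  pre <- expm1(as.matrix(e2))
  expect_equal(unname(colSums(pre)), rep(10000, 6), tolerance = 1e-8)
})

test_that("mast-cell selection follows the >= min_positive marker rule", {
  genes <- c("TPSAB1", "TPSB2", "MS4A2", "CPA3", "OTHER")
  m <- cbind(c(4, 0, 2, 0, 1),   # 2 markers -> selected
             c(0, 0, 0, 0, 9),   # none -> excluded
             c(1, 0, 0, 0, 3),   # 1 marker -> excluded
             c(2, 1, 3, 4, 0))   # all four -> selected
  expr <- normalize_log(toy_counts(m, genes))
  sel <- select_mast_cells(expr)
  expect_equal(sel$is_mast, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(sel$n_markers_positive, c(2L, 0L, 1L, 4L))
  expect_error(select_mast_cells(expr[-4, ]), class = "mastmap_config_error")
})

test_that("CPA3 split is boundary-exact at 1.5 and idempotent", {
  e <- Matrix::Matrix(rbind(CPA3 = c(1.5, 1.51, 0, 3.2)), sparse = TRUE)
  colnames(e) <- paste0("c", 1:4)
  s <- split_cpa3(e)
  expect_equal(s$cpa3_class, c("low", "high", "low", "high"))
  s2 <- split_cpa3(e, s$cell_id)
  expect_identical(s$cpa3_class, s2$cpa3_class)
})

test_that("marker ranking surfaces the planted CPA3-high program", {
  sim <- simulate_counts(seed = 5)
  res <- suppressWarnings(analyze_scrna(sim$counts))
  truth <- sim$truth
  # selection quality against truth among QC survivors
  m <- merge(res$mast, truth, by = "cell_id")
  m <- m[m$passes_qc, ]
  sens <- sum(m$is_mast.x & m$is_mast.y) / sum(m$is_mast.y)
  prec <- sum(m$is_mast.x & m$is_mast.y) / sum(m$is_mast.x)
  expect_gte(sens, 0.9)
  expect_gte(prec, 0.9)
  # split agreement with planted components
  cl <- merge(res$cpa3, truth, by = "cell_id")
  cl <- cl[!is.na(cl$cpa3_class.y), ]
  expect_gte(mean(cl$cpa3_class.x == cl$cpa3_class.y), 0.9)
  # planted 2x program genes in the top 10 with q < 0.05
  prog <- c("CMA1", "HDC", "SLC18A2")
  r <- match(prog, res$markers$gene)
  expect_true(all(r <= 10))
  expect_true(all(res$markers$q_value[r] < 0.05))
})

test_that("a gene identical across classes has zero effect and q ~ 1", {
  set.seed(15)
  n <- 40
  e <- Matrix::Matrix(rbind(FLAT = rep(2, 2 * n),
                            NOISY = rpois(2 * n, 5)), sparse = TRUE)
  colnames(e) <- paste0("c", seq_len(2 * n))
  labels <- setNames(rep(c("high", "low"), each = n), colnames(e))
  out <- rank_markers(e, labels, top_n = Inf)
  i <- match("FLAT", out$gene)
  expect_equal(out$effect[i], 0)
  expect_gte(out$q_value[i], 0.99)
  expect_error(rank_markers(e, setNames(rep("high", 2 * n), colnames(e))),
               class = "mastmap_insufficient_data_error")
})

test_that("label permutation yields no discoveries (small run)", {
  sim <- simulate_counts(n_cells = 1500, seed = 16)
  flt <- suppressWarnings(qc_filter(sim$counts))
  expr <- normalize_log(flt$counts)
  mast <- select_mast_cells(expr)
  ids <- mast$cell_id[mast$is_mast]
  cls <- split_cpa3(expr, ids)
  set.seed(17)
  hits <- vapply(1:5, function(i) {
    perm <- cls
    perm$cpa3_class <- sample(perm$cpa3_class)
    any(rank_markers(expr[, ids], perm, top_n = Inf)$q_value < 0.05)
  }, logical(1))
  expect_lte(sum(hits), 1)
})
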