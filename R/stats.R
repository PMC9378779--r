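# Nonparametric statistics: Mann-Whitney, Kruskal-Wallis + Dunn post-hoc,
# Spearman correlation, significance stars, and the release-capacity fold.

#' Significance stars
#'
#' Maps a p-value to the figure-legend convention: `ns` (p > 0.05), `*`
#' (p <= 0.05), `**` (p <= 0.01), `***` (p <= 0.001), `****` (p <= 0.0001).
#'
#' @param p numeric vector of p-values.
#' @return Character vector of star annotations.
#' @export
signif_stars <- function(p) {
  ifelse(is.na(p), NA_character_,
  ifelse(p <= 1e-4, "****",
  ifelse(p <= 1e-3, "***",
  ifelse(p <= 1e-2, "**",
  ifelse(p <= 5e-2, "*", "ns")))))
}

#' Two-sided Mann-Whitney U test
#'
#' Exact U distribution when both groups have at most 8 observations and no
#' ties; otherwise the normal approximation with tie correction (no
#' continuity correction). The reported statistic is the U of the first
#' sample.
#'
#' @param a,b numeric vectors (each of length >= 3).
#' @param exact_max largest per-group size for the exact null distribution.
#' @return Object of class `mast_test` with the U statistic, two-sided p,
#'   group sizes, medians and IQRs, and star annotation.
#' @export
mann_whitney <- function(a, b, exact_max = 8) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 3 || length(b) < 3) {
    abort("each group needs at least 3 observations",
          class = "mastmap_insufficient_data_error")
  }
  ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- length(a) <= exact_max && length(b) <= exact_max && !ties
  res <- suppressWarnings(
    wilcox.test(a, b, exact = use_exact, correct = FALSE)
  )
  structure(list(
    method = if (use_exact) "mann_whitney_exact" else "mann_whitney_normal",
    statistic = unname(res$statistic),
    p_value = min(1, res$p.value),
    n = c(length(a), length(b)),
    medians = c(median(a), median(b)),
    iqrs = c(stats::IQR(a), stats::IQR(b)),
    stars = signif_stars(res$p.value)
  ), class = "mast_test")
}

#' @export
print.mast_test <- function(x, ...) {
  cat(sprintf("<%s> U = %.4g, n = %d/%d, medians = %.4g/%.4g, p = %.4g %s\n",
              x$method, x$statistic, x$n[1], x$n[2],
              x$medians[1], x$medians[2], x$p_value, x$stars))
  invisible(x)
}

#' Kruskal-Wallis omnibus test with Dunn's post-hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis H, then Dunn's z for every group pair with
#' Bonferroni-adjusted p-values (the Prism convention; adjustment method
#' configurable via [stats::p.adjust()] names).
#'
#' @param groups named list of numeric vectors (>= 3 groups, each n >= 3).
#' @param adjust p-adjustment method for the pairwise tests.
#' @return Object of class `mast_kruskal`: `h`, `df`, `p_value` for the
#'   omnibus and a tibble `pairwise` with z and adjusted p per pair.
#' @export
kruskal_dunn <- function(groups, adjust = study_config()$dunn_adjust) {
  groups <- lapply(groups, function(v) v[!is.na(v)])
  if (length(groups) < 3) {
    abort("fewer than 3 groups: use mann_whitney() for a two-group comparison",
          class = "mastmap_insufficient_data_error")
  }
  if (any(lengths(groups) < 3)) {
    abort("each group needs at least 3 observations",
          class = "mastmap_insufficient_data_error")
  }
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  kw <- kruskal.test(x, g)

  n <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  ni <- lengths(groups)
  t <- table(x)
  tie_term <- sum(t^3 - t)
  sig2_base <- n * (n + 1) / 12 - tie_term / (12 * (n - 1))
  pairs <- utils::combn(names(groups), 2)
  z <- vapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    (rbar[[i]] - rbar[[j]]) / sqrt(sig2_base * (1 / ni[[i]] + 1 / ni[[j]]))
  }, numeric(1))
  p_raw <- 2 * pnorm(-abs(z))
  p_adj <- p.adjust(p_raw, method = adjust)
  pairwise <- tibble::tibble(
    group_a = pairs[1, ], group_b = pairs[2, ],
    z = z, p_raw = p_raw, p_adj = p_adj, stars = signif_stars(p_adj)
  )
  structure(list(h = unname(kw$statistic), df = unname(kw$parameter),
                 p_value = kw$p.value, pairwise = pairwise,
                 adjust = adjust),
            class = "mast_kruskal")
}

#' @export
print.mast_kruskal <- function(x, ...) {
  cat(sprintf("<kruskal_dunn> H = %.4g (df = %d), p = %.4g; %d pairwise (%s)\n",
              x$h, x$df, x$p_value, nrow(x$pairwise), x$adjust))
  print(x$pairwise)
  invisible(x)
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties; exact p for n <= 9 without
#' ties, t approximation otherwise.
#'
#' @param x,y paired numeric vectors (n >= 5 complete pairs).
#' @return Object of class `mast_cor` with `r`, `p_value`, `n`.
#' @export
spearman_cor <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 5) {
    abort("need at least 5 complete pairs",
          class = "mastmap_insufficient_data_error")
  }
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    abort("correlation undefined for a constant vector",
          class = "mastmap_degenerate_error")
  }
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  res <- suppressWarnings(
    cor.test(x, y, method = "spearman", exact = length(x) <= 9 && !ties)
  )
  structure(list(r = unname(res$estimate), p_value = res$p.value,
                 n = length(x), stars = signif_stars(res$p.value)),
            class = "mast_cor")
}

#' @export
print.mast_cor <- function(x, ...) {
  cat(sprintf("<spearman> r = %.4f, n = %d, p = %.4g %s\n",
              x$r, x$n, x$p_value, x$stars))
  invisible(x)
}

#' Theoretical tissue release-capacity fold
#'
#' The total capacity of a tissue to generate a mediator scales with both
#' per-cell expression and cell density; the capacity multiplier is their
#' product. With the reported >4-fold mRNA expression increase and
#' sevenfold density increase in fibrotic distal lung, the capacity fold is
#' 28 — "more than 20 times" baseline.
#'
#' @param expression_fold per-cell expression fold change (> 0).
#' @param density_fold cell-density fold change (> 0).
#' @return The product, a dimensionless fold.
#' @export
capacity_fold <- function(expression_fold, density_fold) {
  if (!is.numeric(expression_fold) || !is.numeric(density_fold) ||
      any(expression_fold <= 0) || any(density_fold <= 0)) {
    abort("folds must be positive numbers", class = "mastmap_validation_error")
  }
  expression_fold * density_fold
}
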