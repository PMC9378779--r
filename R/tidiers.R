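# broom-style tidiers for the package's test objects.

#' Tidy a Mann-Whitney test
#'
#' @param x a `mast_test` from [mann_whitney()] or [compare_rois()].
#' @param ... unused.
#' @return One-row tibble with the statistic, p-value, group sizes, medians
#'   and star annotation.
#' @export
tidy.mast_test <- function(x, ...) {
  tibble::tibble(method = x$method, statistic = x$statistic,
                 p_value = x$p_value, n_a = x$n[1], n_b = x$n[2],
                 median_a = x$medians[1], median_b = x$medians[2],
                 iqr_a = x$iqrs[1], iqr_b = x$iqrs[2], stars = x$stars)
}

#' @rdname tidy.mast_test
#' @export
glance.mast_test <- function(x, ...) tidy.mast_test(x)

#' Tidy a Kruskal-Wallis + Dunn result
#'
#' `tidy()` returns the pairwise Dunn comparisons; `glance()` the omnibus.
#'
#' @param x a `mast_kruskal` from [kruskal_dunn()].
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.mast_kruskal <- function(x, ...) x$pairwise

#' @rdname tidy.mast_kruskal
#' @export
glance.mast_kruskal <- function(x, ...) {
  tibble::tibble(h = x$h, df = x$df, p_value = x$p_value, adjust = x$adjust)
}

#' Tidy a Spearman correlation
#'
#' @param x a `mast_cor` from [spearman_cor()].
#' @param ... unused.
#' @return One-row tibble with r, n, p and stars.
#' @export
tidy.mast_cor <- function(x, ...) {
  tibble::tibble(r = x$r, n = x$n, p_value = x$p_value, stars = x$stars)
}
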