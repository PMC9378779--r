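# Chromogen colour deconvolution (optical-density unmixing) and
# immunoreactive area fractions for brightfield double IHC.

#' Stain model for two-chromogen brightfield IHC
#'
#' Unit-length optical-density vectors for the two chromogens (defaults:
#' the published DAB brown vector and a calibrated Vina-green vector), plus
#' an orthogonal residual vector completing the basis.
#'
#' @param names character vector of two stain names.
#' @param vectors 2 x 3 matrix of per-stain RGB optical densities (rows are
#'   normalised to unit length).
#' @return Object of class `stain_model`: list with `names` and `matrix`
#'   (3 x 3, rows = dab, green, residual).
#' @export
stain_model <- function(names = c("dab", "vina_green"),
                        vectors = rbind(c(0.268, 0.570, 0.776),
                                        c(0.650, 0.200, 0.730))) {
  vectors <- as.matrix(vectors)
  if (nrow(vectors) != 2 || ncol(vectors) != 3) {
    abort("vectors must be a 2 x 3 matrix of RGB optical densities")
  }
  vectors <- vectors / sqrt(rowSums(vectors^2))
  cosang <- abs(sum(vectors[1, ] * vectors[2, ]))
  if (cosang > 0.999) {
    abort("stain vectors are collinear", class = "mastmap_validation_error")
  }
  resid <- c(vectors[1, 2] * vectors[2, 3] - vectors[1, 3] * vectors[2, 2],
             vectors[1, 3] * vectors[2, 1] - vectors[1, 1] * vectors[2, 3],
             vectors[1, 1] * vectors[2, 2] - vectors[1, 2] * vectors[2, 1])
  resid <- resid / sqrt(sum(resid^2))
  m <- rbind(vectors, resid)
  rownames(m) <- c(names, "residual")
  structure(list(names = names, matrix = m), class = "stain_model")
}

rgb_to_od <- function(rgb) -log10((rgb + 1) / 256)
od_to_rgb <- function(od) 256 * 10^(-od) - 1

#' Colour-deconvolve a brightfield RGB image into stain densities
#'
#' Converts 8-bit RGB to optical density per component,
#' `OD = -log10((I + 1) / 256)`, and projects onto the stain basis by matrix
#' inversion (Ruifrok-Johnston deconvolution). Negative stain densities are
#' floored at 0; the residual channel is returned untouched.
#'
#' @param rgb H x W x 3 array of 8-bit values (0-255; fractional values from
#'   a noise-free forward model are accepted).
#' @param model a [stain_model()].
#' @return H x W x 3 array of stain densities (third dimension named after
#'   the stains plus `residual`).
#' @export
deconvolve <- function(rgb, model = stain_model()) {
  stopifnot(inherits(model, "stain_model"))
  d <- dim(rgb)
  if (length(d) != 3 || d[3] != 3) abort("rgb must be an H x W x 3 array")
  od <- rgb_to_od(matrix(rgb, ncol = 3))
  conc <- od %*% solve(model$matrix)
  conc[, 1:2] <- pmax(conc[, 1:2], 0)
  out <- array(conc, dim = d)
  dimnames(out) <- list(NULL, NULL, rownames(model$matrix))
  out
}

#' Compose an RGB image from stain densities (forward model)
#'
#' Beer-Lambert composition: the inverse of [deconvolve()] for noise-free
#' densities (exact up to 8-bit quantisation when `quantize = TRUE`).
#'
#' @param densities H x W x 2 array (or H x W matrix for one stain) of stain
#'   densities.
#' @param model a [stain_model()].
#' @param quantize round to integer 8-bit RGB (default `FALSE`, keeping the
#'   algebraic round trip exact).
#' @return H x W x 3 RGB array.
#' @export
compose_stains <- function(densities, model = stain_model(), quantize = FALSE) {
  d <- dim(densities)
  if (length(d) == 2) {
    densities <- array(c(densities, matrix(0, d[1], d[2])), c(d[1], d[2], 2))
    d <- dim(densities)
  }
  conc <- cbind(matrix(densities, ncol = 2), 0)
  od <- conc %*% model$matrix
  rgb <- od_to_rgb(od)
  if (quantize) rgb <- pmin(255, pmax(0, round(rgb)))
  array(rgb, c(d[1], d[2], 3))
}

#' Immunoreactive area fraction
#'
#' Fraction of tissue pixels whose stain optical density reaches the locked
#' threshold — immunoreactivity normalised to the total analysed tissue
#' area.
#'
#' @param stain_channel matrix of stain densities (one slice of
#'   [deconvolve()] output).
#' @param od_threshold optical-density threshold (default from
#'   [study_config()]).
#' @param tissue logical tissue mask, same dimensions.
#' @return Fraction in `[0, 1]`.
#' @export
area_fraction <- function(stain_channel, od_threshold = study_config()$od_threshold,
                          tissue = NULL) {
  if (is.null(tissue)) tissue <- matrix(TRUE, nrow(stain_channel), ncol(stain_channel))
  if (!any(tissue)) {
    abort("empty tissue mask", class = "mastmap_degenerate_error")
  }
  sum(stain_channel[tissue] >= od_threshold) / sum(tissue)
}

#' Quantify a double-chromogen slide
#'
#' Deconvolves the slide and returns both stains' immunoreactive area
#' fractions over the tissue mask.
#'
#' @param rgb H x W x 3 8-bit RGB array.
#' @param model a [stain_model()].
#' @param od_threshold optical-density threshold.
#' @param tissue logical tissue mask (default: whole frame).
#' @return Tibble with columns `stain`, `area_fraction`, `area_percent`.
#' @export
quantify_chromogens <- function(rgb, model = stain_model(),
                                od_threshold = study_config()$od_threshold,
                                tissue = NULL) {
  dec <- deconvolve(rgb, model)
  tibble::tibble(
    stain = model$names,
    area_fraction = vapply(seq_along(model$names), function(i) {
      area_fraction(dec[, , i], od_threshold, tissue)
    }, numeric(1))
  ) |>
    dplyr::mutate(area_percent = 100 * .data$area_fraction)
}
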