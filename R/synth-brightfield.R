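# Synthetic double-chromogen brightfield slides with exact planted
# area fractions.

#' Simulate a double-IHC brightfield slide
#'
#' Plants non-overlapping blob regions of DAB-like and green-chromogen-like
#' absorbance on a near-white tissue background, composed via Beer-Lambert
#' mixing with the stain model's vectors and quantised to 8-bit RGB. The
#' planted pixel masks are trimmed to hit the requested area fractions
#' exactly (to one pixel), and the recorded truth is the realised planted
#' fraction counted directly from the masks.
#'
#' @param target_fractions numeric vector of two target area fractions
#'   (dab, green); each >= 0, sum <= 0.5.
#' @param seed RNG seed.
#' @param width_px,height_px slide dimensions in pixels.
#' @param model a [stain_model()].
#' @param stain_od nominal optical density of planted chromogen (per-pixel
#'   density varies uniformly within +/- 25%).
#' @param tissue_od neutral optical density of unstained tissue.
#' @param noise_sd Gaussian RGB noise SD in 8-bit counts.
#' @return List with `rgb` (H x W x 3 integer array), `truth` (tibble:
#'   stain, fraction), `masks` (list of planted logical masks), `tissue`
#'   (logical mask, whole frame).
#' @export
simulate_brightfield <- function(target_fractions = c(dab = 0.10, vina_green = 0.05),
                                 seed = 1, width_px = 400, height_px = 400,
                                 model = stain_model(), stain_od = 0.8,
                                 tissue_od = 0.04, noise_sd = 1) {
  if (length(target_fractions) != 2 || any(target_fractions < 0) ||
      sum(target_fractions) > 0.5) {
    abort("target_fractions must be two fractions >= 0 summing to <= 0.5",
          class = "mastmap_validation_error")
  }
  H <- height_px; W <- width_px; N <- H * W
  with_seed(seed, {
    taken <- matrix(FALSE, H, W)
    masks <- list()
    for (s in 1:2) {
      need <- round(target_fractions[s] * N)
      mask <- matrix(FALSE, H, W)
      guard <- 0
      while (sum(mask) < need && guard < 10000) {
        guard <- guard + 1
        r <- runif(1, 5, 15)
        cx <- runif(1, 1, W); cy <- runif(1, 1, H)
        c0 <- max(1, floor(cx - r)); c1 <- min(W, ceiling(cx + r))
        r0 <- max(1, floor(cy - r)); r1 <- min(H, ceiling(cy + r))
        dd <- outer(((r0:r1) - cy)^2, ((c0:c1) - cx)^2, "+") <= r^2
        sel <- which(dd)
        rr <- r0 + (sel - 1) %% (r1 - r0 + 1)
        cc <- c0 + (sel - 1) %/% (r1 - r0 + 1)
        lin <- (cc - 1) * H + rr
        lin <- lin[!taken[lin] & !mask[lin]]
        if (!length(lin)) next
        excess <- (sum(mask) + length(lin)) - need
        if (excess > 0) lin <- lin[seq_len(length(lin) - excess)]
        mask[lin] <- TRUE
      }
      taken <- taken | mask
      masks[[s]] <- mask
    }
    names(masks) <- model$names

    dens <- array(0, c(H, W, 2))
    for (s in 1:2) {
      idx <- which(masks[[s]])
      slice <- matrix(0, H, W)
      slice[idx] <- stain_od * runif(length(idx), 0.75, 1.25)
      dens[, , s] <- slice
    }
    # neutral gray tissue absorbance over the whole frame
    conc <- cbind(matrix(dens, ncol = 2), 0)
    od <- conc %*% model$matrix + matrix(tissue_od / sqrt(3), N, 3)
    rgb <- od_to_rgb(od)
    if (noise_sd > 0) rgb <- rgb + rnorm(length(rgb), 0, noise_sd)
    rgb <- array(pmin(255, pmax(0, round(rgb))), c(H, W, 3))

    truth <- tibble::tibble(
      stain = model$names,
      fraction = unname(vapply(masks, function(m) sum(m) / N, numeric(1)))
    )
    list(rgb = rgb, truth = truth, masks = masks,
         tissue = matrix(TRUE, H, W))
  })
}
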