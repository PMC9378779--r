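# Render a synthetic multichannel section with known ground truth.

#' Simulate a multiplex-stained tissue section
#'
#' Plants elliptical tryptase-positive mast cells compartment-by-compartment
#' at the preset densities, draws each cell's true mRNA and protein level
#' from the preset mixture distributions, and renders the four channels:
#' tryptase and protein as filled ellipses, mRNA as punctate RNAscope-like
#' dots (Poisson count proportional to the true level) or as a diffuse fill,
#' on top of a constant autofluorescence background, a smooth background
#' field, and Gaussian read noise. Channels are quantised to integer AU
#' (16-bit range). Pure function of `(layout, preset, imaging, seed)`.
#'
#' @param layout a [compartment_annotation()] from
#'   [make_compartment_layout()] (needs `width_um`/`height_um` attributes).
#' @param preset a [group_preset()].
#' @param imaging an [imaging_params()].
#' @param seed RNG seed.
#' @param mrna_shift,protein_shift multiplicative patient-level shifts
#'   applied to all intensity medians (used by [simulate_cohort()]).
#' @param patient_id,section_id identifiers stamped on the ground truth.
#' @return Object of class `synthetic_section`: a list with `image`
#'   ([multiplex_image()]), `truth` (tibble of planted cells: centroid,
#'   area, compartment, true levels, dot count, overlap flag), `truth_mask`
#'   (logical matrix of planted cell pixels), and `layout`.
#' @export
simulate_section <- function(layout, preset, imaging = imaging_params(),
                             seed = 1, mrna_shift = 1, protein_shift = 1,
                             patient_id = "patient", section_id = NULL) {
  stopifnot(inherits(layout, "compartment_annotation"),
            inherits(preset, "group_preset"))
  width_um <- attr(layout, "width_um")
  height_um <- attr(layout, "height_um")
  if (is.null(width_um) || is.null(height_um)) {
    abort("layout lacks width_um/height_um attributes")
  }
  px <- imaging$pixel_size_um
  W <- as.integer(round(width_um / px))
  H <- as.integer(round(height_um / px))
  section_id <- section_id %||% attr(layout, "section_id")

  mean_area <- mean(imaging$area_range_um2)
  eff <- region_effective_areas(layout)
  # refuse densities that would force heavy cell overlap
  for (i in seq_len(nrow(layout))) {
    lab <- layout$label[i]
    if (lab == "excluded") next
    d <- preset$compartments$density_cells_per_mm2[
      preset$compartments$compartment == lab]
    if (length(d) == 0) next
    if (d * mean_area * 1e-6 > 0.3) {
      abort(sprintf(
        "density %.0f cells/mm2 in '%s' implies > 0.3 planted overlap fraction",
        d, lab), class = "mastmap_generation_error")
    }
  }

  with_seed(seed, {
    tryp <- matrix(0, H, W)
    prot <- matrix(0, H, W)
    mrna <- matrix(0, H, W)
    truth_mask <- matrix(FALSE, H, W)
    dot_lin <- list()

    xs <- numeric(0); ys <- numeric(0); rs <- numeric(0)
    # truth-table accumulators (one tibble built at the end)
    t_x <- numeric(0); t_y <- numeric(0); t_area <- numeric(0)
    t_comp <- character(0); t_mrna <- numeric(0); t_prot <- numeric(0)
    t_high <- logical(0); t_amp <- numeric(0); t_dots <- integer(0)
    t_over <- logical(0)
    cell_id <- 0L

    for (i in seq_len(nrow(layout))) {
      lab <- layout$label[i]
      if (lab == "excluded") next
      prow <- preset$compartments[preset$compartments$compartment == lab, ]
      if (nrow(prow) == 0 || prow$density_cells_per_mm2 <= 0) next
      n_target <- rpois(1, prow$density_cells_per_mm2 * eff[i] / 1e6)
      if (n_target == 0) next
      poly <- layout$polygon[[i]]
      bb <- apply(poly, 2, range)

      for (k in seq_len(n_target)) {
        area <- runif(1, imaging$area_range_um2[1], imaging$area_range_um2[2])
        aspect <- runif(1, 0.7, 1)
        th <- runif(1, 0, pi)
        a <- sqrt(area / (pi * aspect)); b <- a * aspect # semi-axes, um
        r_eq <- sqrt(area / pi)
        rmax <- max(a, b)
        pos <- NULL; overlapping <- FALSE
        lox <- max(bb[1, 1], rmax + 2 * px)
        hix <- min(bb[2, 1], width_um - rmax - 2 * px)
        loy <- max(bb[1, 2], rmax + 2 * px)
        hiy <- min(bb[2, 2], height_um - rmax - 2 * px)
        if (lox >= hix || loy >= hiy) next
        for (try in seq_len(40)) {
          cx <- runif(1, lox, hix)
          cy <- runif(1, loy, hiy)
          if (!point_in_polygon(cx, cy, poly)) next
          if (assign_region_index(cx, cy, layout, "innermost") != i) next
          if (length(xs)) {
            sep <- sqrt((xs - cx)^2 + (ys - cy)^2)
            if (any(sep < imaging$min_sep_factor * (rs + r_eq))) {
              pos <- c(cx, cy) # remember a valid-but-close position
              overlapping <- TRUE
              next
            }
          }
          pos <- c(cx, cy); overlapping <- FALSE
          break
        }
        if (is.null(pos)) next # no in-compartment position found
        cx <- pos[1]; cy <- pos[2]
        xs <- c(xs, cx); ys <- c(ys, cy); rs <- c(rs, r_eq)

        # true expression levels: base/high mixture for mRNA
        is_high <- runif(1) < prow$frac_mrna_high
        med <- if (is_high) preset$mrna_high_median else prow$mrna_base_median
        mrna_true <- rlnorm(1, log(med * mrna_shift), preset$mrna_sigma)
        protein_true <- rlnorm(1, log(prow$protein_median * protein_shift),
                               preset$protein_sigma)
        amp <- rlnorm(1, log(imaging$tryptase_median), imaging$tryptase_sigma)

        # rasterise the ellipse
        c0 <- max(1L, floor((cx - rmax) / px)); c1 <- min(W, ceiling((cx + rmax) / px))
        r0 <- max(1L, floor((cy - rmax) / px)); r1 <- min(H, ceiling((cy + rmax) / px))
        dx <- ((c0:c1) - 0.5) * px - cx
        dy <- ((r0:r1) - 0.5) * px - cy
        ct <- cos(th); st <- sin(th)
        U <- outer(dy, dx, function(y, x) (x * ct + y * st) / a)
        V <- outer(dy, dx, function(y, x) (-x * st + y * ct) / b)
        sel <- which(U * U + V * V <= 1)
        if (length(sel) == 0) next
        nbr <- r1 - r0 + 1L
        rr <- r0 + (sel - 1L) %% nbr
        cc <- c0 + (sel - 1L) %/% nbr
        lin <- (cc - 1L) * H + rr
        tryp[lin] <- tryp[lin] + amp
        prot[lin] <- prot[lin] + imaging$protein_gain * protein_true
        truth_mask[lin] <- TRUE

        area_px <- length(sel) * px^2
        n_dots <- 0L
        if (imaging$mrna_render == "diffuse") {
          mrna[lin] <- mrna[lin] + imaging$mrna_gain * mrna_true
        } else {
          # dot count ~ transcript density x cell area, so the mean rendered
          # intensity over the cell tracks the true level irrespective of size
          n_dots <- rpois(1, imaging$dot_density_per_au * mrna_true * area_px)
          if (n_dots > 0) {
            # dots are intracellular: keep centres ~1.5 px inside the cell
            # rim so their Gaussian mass stays within the tryptase ROI
            inset <- 1.5 * px
            a_in <- max(a - inset, 0.4 * a)
            b_in <- max(b - inset, 0.4 * b)
            rad <- sqrt(runif(n_dots)); phi <- runif(n_dots, 0, 2 * pi)
            ex <- a_in * rad * cos(phi); ey <- b_in * rad * sin(phi)
            xd <- cx + ex * ct - ey * st
            yd <- cy + ex * st + ey * ct
            dc <- pmin(W, pmax(1L, as.integer(ceiling(xd / px))))
            dr <- pmin(H, pmax(1L, as.integer(ceiling(yd / px))))
            dot_lin[[length(dot_lin) + 1L]] <- (dc - 1L) * H + dr
          }
        }

        cell_id <- cell_id + 1L
        t_x[cell_id] <- cx; t_y[cell_id] <- cy; t_area[cell_id] <- area_px
        t_comp[cell_id] <- lab; t_mrna[cell_id] <- mrna_true
        t_prot[cell_id] <- protein_true; t_high[cell_id] <- is_high
        t_amp[cell_id] <- amp; t_dots[cell_id] <- n_dots
        t_over[cell_id] <- overlapping
      }
    }

    if (length(dot_lin)) {
      lin <- unlist(dot_lin, use.names = FALSE)
      u <- sort(unique(lin))
      cnt <- tabulate(match(lin, u), length(u))
      s <- imaging$dot_sigma_px
      half <- max(3L, ceiling(3 * s))
      # sparse convolution: stamp the Gaussian dot profile at each occupied
      # pixel (dots are a tiny fraction of the image; no FFT needed)
      ur <- ((u - 1L) %% H) + 1L
      uc <- ((u - 1L) %/% H) + 1L
      for (dr in (-half):half) {
        kr <- exp(-dr^2 / (2 * s^2))
        for (dc in (-half):half) {
          k <- imaging$dot_amplitude * kr * exp(-dc^2 / (2 * s^2))
          rr <- ur + dr; cc <- uc + dc
          okp <- rr >= 1L & rr <= H & cc >= 1L & cc <= W
          tgt <- (cc[okp] - 1L) * H + rr[okp]
          mrna[tgt] <- mrna[tgt] + k * cnt[okp]
        }
      }
    }

    # backgrounds: constant autofluorescence + smooth field, per signal channel
    bgf <- matrix(0, H, W)
    if (imaging$background_field_amp > 0) {
      phx <- runif(1, 0, 2 * pi); phy <- runif(1, 0, 2 * pi)
      bgf <- imaging$background_field_amp *
        outer(sin(2 * pi * (1:H) / H + phy), sin(2 * pi * (1:W) / W + phx))
    }
    bg <- imaging$background + bgf
    nuc <- matrix(imaging$nuclei_level, H, W)
    quantise <- function(m) {
      if (imaging$noise_sd > 0) {
        m <- m + matrix(rnorm(H * W, 0, imaging$noise_sd), H, W)
      }
      if (imaging$quantize) m <- round(m)
      matrix(pmin(65535, pmax(0, m)), H, W)
    }
    img <- multiplex_image(
      list(nuclei = quantise(nuc), mrna = quantise(mrna + bg),
           protein = quantise(prot + bg), tryptase = quantise(tryp + bg)),
      pixel_size_um = px, source_id = section_id)

    n_cells <- cell_id
    truth <- tibble::tibble(
      cell_id = seq_len(n_cells),
      patient_id = rep(patient_id, n_cells),
      section_id = rep(section_id, n_cells),
      x_um = t_x, y_um = t_y, area_um2 = t_area,
      compartment = t_comp, mrna_true = t_mrna,
      protein_true = t_prot, mrna_high_true = t_high,
      tryptase_amp = t_amp, n_dots = t_dots, overlaps = t_over)

    structure(list(image = img, truth = truth, truth_mask = truth_mask,
                   layout = layout),
              class = "synthetic_section")
  })
}

#' @export
print.synthetic_section <- function(x, ...) {
  cat(sprintf("<synthetic_section> %s: %d planted cells, %d x %d px\n",
              x$image$source_id, nrow(x$truth),
              nrow(x$truth_mask), ncol(x$truth_mask)))
  invisible(x)
}
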