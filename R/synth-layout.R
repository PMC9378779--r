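# Synthetic compartment layouts: airways (lumen + epithelial ring +
# subepithelial annulus), pulmonary vessels, and an alveolar-parenchyma
# remainder.

#' Generate a synthetic compartment layout
#'
#' Places one or more small airways (concentric lumen/epithelium/
#' subepithelium discs), elliptical pulmonary vessels, and a section-wide
#' alveolar-parenchyma region. Nested structures are represented as stacked
#' simple polygons resolved innermost-first by the assignment rule; the
#' airway lumen is an `excluded` region so no cells are planted or assigned
#' there. Deterministic for a fixed seed.
#'
#' @param width_um,height_um section dimensions in micrometres (> 200).
#' @param seed RNG seed.
#' @param n_airways,n_vessels structure counts; defaults scale with section
#'   area (about one of each per 1.5 mm^2, at least one each).
#' @return A [compartment_annotation()] with attributes `width_um` and
#'   `height_um`.
#' @export
make_compartment_layout <- function(width_um, height_um, seed = 1,
                                    n_airways = NULL, n_vessels = NULL) {
  if (width_um <= 200 || height_um <= 200) {
    abort("section must exceed 200 um in both dimensions",
          class = "mastmap_generation_error")
  }
  area_mm2 <- width_um * height_um / 1e6
  n_airways <- n_airways %||% max(1L, round(area_mm2 / 1.5))
  n_vessels <- n_vessels %||% max(1L, round(area_mm2 / 1.5))

  with_seed(seed, {
    margin <- 20
    # outer radii of all structures, drawn up front
    airway_scale <- runif(n_airways, 0.85, 1.15)
    vessel_a <- 120 * runif(n_vessels, 0.8, 1.2)
    vessel_b <- 70 * runif(n_vessels, 0.8, 1.2)
    vessel_th <- runif(n_vessels, 0, pi)
    radii <- c(150 * airway_scale, pmax(vessel_a, vessel_b))
    if (any(2 * (radii + margin) > min(width_um, height_um))) {
      abort("section too small to place the mandatory airway/vessel structures",
            class = "mastmap_generation_error")
    }

    # rejection-sample a non-overlapping arrangement, restarting the whole
    # arrangement when a structure cannot be placed (a central first
    # structure can otherwise block all later ones)
    centres <- NULL
    for (attempt in seq_len(60)) {
      placed <- matrix(numeric(0), ncol = 3)
      ok_all <- TRUE
      for (r_outer in radii) {
        ok <- FALSE
        for (try in seq_len(200)) {
          cx <- runif(1, r_outer + margin, width_um - r_outer - margin)
          cy <- runif(1, r_outer + margin, height_um - r_outer - margin)
          if (nrow(placed) == 0 ||
              all(sqrt((placed[, 1] - cx)^2 + (placed[, 2] - cy)^2) >=
                    r_outer + placed[, 3] + 10)) {
            placed <- rbind(placed, c(cx, cy, r_outer))
            ok <- TRUE
            break
          }
        }
        if (!ok) { ok_all <- FALSE; break }
      }
      if (ok_all) { centres <- placed; break }
    }
    if (is.null(centres)) {
      abort("section too small to place the mandatory airway/vessel structures",
            class = "mastmap_generation_error")
    }

    labels <- character(0)
    polys <- list()
    for (i in seq_len(n_airways)) {
      s <- airway_scale[i]
      ctr <- centres[i, 1:2]
      labels <- c(labels, "excluded", "airway_epithelium", "airway_subepithelium")
      polys <- c(polys, list(circle_polygon(ctr[1], ctr[2], 60 * s),
                             circle_polygon(ctr[1], ctr[2], 90 * s),
                             circle_polygon(ctr[1], ctr[2], 150 * s)))
    }
    for (i in seq_len(n_vessels)) {
      ctr <- centres[n_airways + i, 1:2]
      labels <- c(labels, "pulmonary_vessel")
      polys <- c(polys, list(ellipse_polygon(ctr[1], ctr[2], vessel_a[i],
                                             vessel_b[i], vessel_th[i])))
    }
    labels <- c(labels, "alveolar_parenchyma")
    polys <- c(polys, list(rect_polygon(0, 0, width_um, height_um)))

    ann <- compartment_annotation(labels, polys,
                                  section_id = sprintf("synthetic_%d", seed))
    attr(ann, "width_um") <- width_um
    attr(ann, "height_um") <- height_um
    ann
  })
}
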