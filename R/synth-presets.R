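# Disease-group presets for the synthetic cohort generator.
#
# The generator mirrors the reported disease biology as planted effect sizes:
# relative to control mast cells, COPD cells raise CPA3 mRNA threefold in
# small airways and twofold in vessels (1.7x in parenchyma) with unaltered
# protein; IPF parenchyma raises mRNA 3.2-fold together with 1.8-fold protein
# and a sevenfold mast-cell density increase. The fraction of mRNA-high cells
# is planted explicitly as a mixture component (base log-normal population
# plus a "high" population at a fixed median), so the locked-threshold gate
# recovers a fraction that is robust to patient-level random effects:
# under 5% of control cells are mRNA-high versus ~40% of the IPF pool.

#' Construct a synthetic disease-group preset
#'
#' @param name group name (`control`, `copd`, `ipf`).
#' @param compartments tibble with one row per compartment and columns
#'   `compartment`, `density_cells_per_mm2`, `mrna_base_median` (AU),
#'   `frac_mrna_high`, `protein_median` (AU).
#' @param mrna_high_median median mRNA level (AU) of the planted mRNA-high
#'   mixture component.
#' @param mrna_sigma,protein_sigma log-normal cell-to-cell dispersion
#'   (SD of log intensity) of the intensity distributions.
#' @return Object of class `group_preset`.
#' @export
group_preset <- function(name, compartments, mrna_high_median = 700,
                         mrna_sigma = 0.25, protein_sigma = 0.25) {
  need <- c("compartment", "density_cells_per_mm2", "mrna_base_median",
            "frac_mrna_high", "protein_median")
  missing <- setdiff(need, names(compartments))
  if (length(missing)) {
    abort(sprintf("preset compartments table missing: %s",
                  paste(missing, collapse = ", ")))
  }
  if (any(compartments$density_cells_per_mm2 < 0) ||
      any(compartments$mrna_base_median <= 0) ||
      any(compartments$protein_median <= 0) ||
      any(compartments$frac_mrna_high < 0 | compartments$frac_mrna_high > 1)) {
    abort("preset values out of range: densities >= 0, medians > 0, fractions in [0,1]")
  }
  structure(list(name = name, compartments = tibble::as_tibble(compartments),
                 mrna_high_median = mrna_high_median,
                 mrna_sigma = mrna_sigma, protein_sigma = protein_sigma),
            class = "group_preset")
}

# Base medians are solved so the planted group-mean mRNA fold over control
# equals the target exactly in expectation:
#   mean = ((1 - f) * Mb + f * Mh) * exp(sigma^2 / 2),
# and the log-normal factor cancels in every fold.
solve_base_median <- function(target_mean, frac_high, high_median) {
  mb <- (target_mean - frac_high * high_median) / (1 - frac_high)
  if (mb <= 0) abort("infeasible preset: high-fraction mixture exceeds target mean")
  mb
}

#' Default control/COPD/IPF presets
#'
#' Control mast cells express a base mRNA median of 100 AU in every
#' compartment with 0.5% mRNA-high cells. COPD multiplies the group-mean
#' mRNA by 3 (airway epithelium and subepithelium), 2 (vessels) and 1.7
#' (parenchyma) with 10% mRNA-high cells and unaltered protein; IPF
#' multiplies parenchymal mRNA by 3.2 and protein by 1.8, plants 40%
#' mRNA-high cells in the parenchyma and a sevenfold parenchymal density
#' increase.
#'
#' @param control_mrna_median base mRNA median (AU) of control cells.
#' @param control_protein_median base protein median (AU).
#' @param high_median median of the mRNA-high mixture component (AU).
#' @return Named list of three [group_preset()] objects.
#' @export
default_presets <- function(control_mrna_median = 100,
                            control_protein_median = 100,
                            high_median = 700) {
  comps <- c("airway_epithelium", "airway_subepithelium",
             "pulmonary_vessel", "alveolar_parenchyma")
  dens <- c(250, 400, 400, 120)
  f_ctrl <- 0.005
  ctrl_mean <- (1 - f_ctrl) * control_mrna_median + f_ctrl * high_median

  make <- function(name, mrna_fold, frac_high, protein_fold, density_fold) {
    tab <- tibble::tibble(
      compartment = comps,
      density_cells_per_mm2 = dens * density_fold,
      mrna_base_median = mapply(function(fold, f) {
        solve_base_median(fold * ctrl_mean, f, high_median)
      }, mrna_fold, frac_high),
      frac_mrna_high = frac_high,
      protein_median = control_protein_median * protein_fold
    )
    group_preset(name, tab, mrna_high_median = high_median)
  }

  list(
    control = make("control",
                   mrna_fold = c(1, 1, 1, 1),
                   frac_high = rep(f_ctrl, 4),
                   protein_fold = c(1, 1, 1, 1),
                   density_fold = c(1, 1, 1, 1)),
    copd = make("copd",
                mrna_fold = c(3, 3, 2, 1.7),
                frac_high = rep(0.10, 4),
                protein_fold = c(1, 1, 1, 1),
                density_fold = c(1, 1, 1, 1)),
    ipf = make("ipf",
               mrna_fold = c(1, 1, 1, 3.2),
               frac_high = c(0.05, 0.05, 0.05, 0.40),
               protein_fold = c(1, 1, 1, 1.8),
               density_fold = c(1, 1, 1, 7))
  )
}

#' Expected planted group means of a preset
#'
#' Closed-form expectations of the planted per-cell levels (no simulation),
#' for verifying preset arithmetic and fold targets.
#'
#' @param preset a [group_preset()].
#' @return Tibble with `compartment`, `mrna_mean`, `protein_mean`,
#'   `density_cells_per_mm2`.
#' @export
preset_expected_means <- function(preset) {
  k_m <- exp(preset$mrna_sigma^2 / 2)
  k_p <- exp(preset$protein_sigma^2 / 2)
  with(preset$compartments, tibble::tibble(
    compartment = compartment,
    mrna_mean = ((1 - frac_mrna_high) * mrna_base_median +
                   frac_mrna_high * preset$mrna_high_median) * k_m,
    protein_mean = protein_median * k_p,
    density_cells_per_mm2 = density_cells_per_mm2
  ))
}

#' Imaging parameters of the synthetic scanner
#'
#' Controls how planted cells are rendered into the four channels: mast cells
#' are elliptical tryptase-positive blobs; mRNA renders as RNAscope-like
#' punctate dots (Poisson count proportional to the true level, Gaussian
#' spot profile); protein renders as a diffuse fill proportional to the true
#' level. All channels receive a constant autofluorescence background, a
#' low-frequency background field, and Gaussian read noise, then quantise to
#' integer AU.
#'
#' @param pixel_size_um micrometres per pixel.
#' @param background constant autofluorescence level (AU).
#' @param background_field_amp amplitude of the smooth background field (AU).
#' @param noise_sd Gaussian read-noise SD (AU).
#' @param nuclei_level tissue signal level of the nuclei channel (AU).
#' @param tryptase_median,tryptase_sigma log-normal tryptase blob amplitude.
#' @param dot_density_per_au expected mRNA dots per square micrometre of
#'   cell area per AU of true mRNA level. Dot count scales with both level
#'   and cell area (a transcript *density*), so the mean intensity over a
#'   cell tracks the true level independently of cell size, as for a
#'   real-intensity measurand.
#' @param dot_amplitude peak amplitude of one rendered dot (AU); the default
#'   pairs with `dot_density_per_au` so the expected mean rendered intensity
#'   equals the true level (2 * pi * sigma^2 * amplitude * density = 1).
#' @param dot_sigma_px Gaussian dot radius in pixels.
#' @param protein_gain,mrna_gain AU of rendered signal per AU of true level
#'   (mrna_gain applies in diffuse mode only).
#' @param mrna_render `"puncta"` (default, RNAscope-like) or `"diffuse"`
#'   (deterministic fill, used for noise-free recovery analyses).
#' @param quantize round channels to integer AU (16-bit scanner behaviour,
#'   the default); disable for exact-arithmetic recovery oracles.
#' @param area_range_um2 uniform range of planted cell areas.
#' @param min_sep_factor minimum centre separation between planted cells as a
#'   fraction of the sum of their equivalent radii; close pairs below contact
#'   distance still merge in the rendered mask, so segmentation faces real
#'   merges, but pathological stacking is avoided.
#' @return Object of class `imaging_params`.
#' @export
imaging_params <- function(pixel_size_um = 1, background = 40,
                           background_field_amp = 8, noise_sd = 10,
                           nuclei_level = 150,
                           tryptase_median = 1000, tryptase_sigma = 0.3,
                           dot_density_per_au = 0.02,
                           dot_amplitude = 1 / (dot_density_per_au * 2 * pi *
                                                  dot_sigma_px^2),
                           dot_sigma_px = 1, protein_gain = 1, mrna_gain = 1,
                           mrna_render = c("puncta", "diffuse"),
                           quantize = TRUE,
                           area_range_um2 = c(50, 250),
                           min_sep_factor = 0.9) {
  structure(list(
    pixel_size_um = pixel_size_um, background = background,
    background_field_amp = background_field_amp, noise_sd = noise_sd,
    nuclei_level = nuclei_level, tryptase_median = tryptase_median,
    tryptase_sigma = tryptase_sigma, dot_density_per_au = dot_density_per_au,
    dot_amplitude = dot_amplitude, dot_sigma_px = dot_sigma_px,
    protein_gain = protein_gain, mrna_gain = mrna_gain,
    mrna_render = match.arg(mrna_render), quantize = quantize,
    area_range_um2 = area_range_um2, min_sep_factor = min_sep_factor
  ), class = "imaging_params")
}
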