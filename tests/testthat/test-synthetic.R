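test_that("layouts contain all compartments and are seed-deterministic", {
  lay <- make_compartment_layout(2000, 2000, seed = 1)
  expect_setequal(unique(lay$label),
                  c("excluded", "airway_epithelium", "airway_subepithelium",
                    "pulmonary_vessel", "alveolar_parenchyma"))
  lay2 <- make_compartment_layout(2000, 2000, seed = 1)
  expect_identical(lay$polygon, lay2$polygon)
  expect_error(make_compartment_layout(150, 2000),
               class = "mastmap_generation_error")
})

test_that("layout region areas partition the section", {
  lay <- make_compartment_layout(1500, 1500, seed = 5)
  eff <- mastmap:::region_effective_areas(lay)
  # effective areas tile the rectangle (polygonal circles only approximate,
  # but the construction is exact: each disc is carved from its parent)
  expect_equal(sum(eff), 1500 * 1500, tolerance = 1e-9)
  expect_true(all(eff > 0))
  # raw areas never exceed the section
  raw <- vapply(lay$polygon, polygon_area, numeric(1))
  expect_true(all(raw <= 1500 * 1500 + 1e-6))
})

test_that("sections are pure functions of their seed", {
  lay <- make_compartment_layout(600, 600, seed = 2)
  s1 <- simulate_section(lay, default_presets()$copd, seed = 9)
  s2 <- simulate_section(lay, default_presets()$copd, seed = 9)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$image$channels, s2$image$channels)
  s3 <- simulate_section(lay, default_presets()$copd, seed = 10)
  expect_false(identical(s1$truth, s3$truth))
})

test_that("zero-density presets give pure-background sections", {
  p0 <- group_preset("none", tibble::tibble(
    compartment = "alveolar_parenchyma", density_cells_per_mm2 = 0,
    mrna_base_median = 100, frac_mrna_high = 0, protein_median = 100))
  lay <- make_compartment_layout(600, 600, seed = 2)
  s <- simulate_section(lay, p0,
                        imaging_params(noise_sd = 0, background = 0,
                                       background_field_amp = 0), seed = 1)
  expect_equal(nrow(s$truth), 0)
  expect_equal(max(s$image$channels$tryptase), 0)
  expect_equal(max(s$image$channels$mrna), 0)
})

test_that("a single noiseless cell is tryptase-positive inside, zero outside", {
  p1 <- group_preset("one", tibble::tibble(
    compartment = "alveolar_parenchyma", density_cells_per_mm2 = 15,
    mrna_base_median = 100, frac_mrna_high = 0, protein_median = 100))
  lay <- compartment_annotation("alveolar_parenchyma",
                                list(rect_poly(0, 0, 600, 600)))
  attr(lay, "width_um") <- 600; attr(lay, "height_um") <- 600
  s <- simulate_section(lay, p1,
                        imaging_params(noise_sd = 0, background = 0,
                                       background_field_amp = 0), seed = 3)
  expect_gt(nrow(s$truth), 0)
  tr <- s$image$channels$tryptase
  expect_gt(mean(tr[s$truth_mask]), 0)
  expect_equal(max(tr[!s$truth_mask]), 0)
})

test_that("excessive density triggers the overlap guard", {
  pX <- group_preset("dense", tibble::tibble(
    compartment = "alveolar_parenchyma", density_cells_per_mm2 = 4000,
    mrna_base_median = 100, frac_mrna_high = 0, protein_median = 100))
  lay <- make_compartment_layout(600, 600, seed = 2)
  expect_error(simulate_section(lay, pX, seed = 1),
               class = "mastmap_generation_error")
})

test_that("rendered mRNA signal is self-consistent with planted levels", {
  sec <- default_section()
  tr <- sec$truth
  expect_gt(nrow(tr), 200)
  # integrated dot count per unit area tracks the true level
  expect_gte(cor(tr$n_dots / tr$area_um2, tr$mrna_true), 0.95)
})

test_that("preset arithmetic plants the reported folds exactly", {
  pr <- default_presets()
  em <- lapply(pr, preset_expected_means)
  fold <- function(comp, what = "mrna_mean", g = "copd") {
    em[[g]][[what]][em[[g]]$compartment == comp] /
      em$control[[what]][em$control$compartment == comp]
  }
  expect_equal(fold("airway_epithelium"), 3)
  expect_equal(fold("airway_subepithelium"), 3)
  expect_equal(fold("pulmonary_vessel"), 2)
  expect_equal(fold("alveolar_parenchyma"), 1.7)
  expect_equal(fold("alveolar_parenchyma", g = "ipf"), 3.2)
  expect_equal(fold("alveolar_parenchyma", "protein_mean", "ipf"), 1.8)
  expect_equal(fold("alveolar_parenchyma", "protein_mean", "copd"), 1)
  expect_equal(fold("alveolar_parenchyma", "density_cells_per_mm2", "ipf"), 7)
})

test_that("cohort truth tables recover planted folds and are deterministic", {
  co <- simulate_cohort(n_patients = c(control = 4, copd = 4, ipf = 3),
                        seed = 7, width_um = 900, height_um = 900,
                        keep_images = FALSE)
  co2 <- simulate_cohort(n_patients = c(control = 4, copd = 4, ipf = 3),
                         seed = 7, width_um = 900, height_um = 900,
                         keep_images = FALSE)
  expect_identical(co$truth, co2$truth)
  expect_equal(nrow(co$patients), 11)
  # parenchymal density fold, truth side (Poisson counting error only)
  tr <- co$truth
  area <- aggregate(mrna_true ~ group, tr[tr$compartment == "alveolar_parenchyma", ],
                    length)
  dens_fold <- area$mrna_true[area$group == "ipf"] / 3 /
    (area$mrna_true[area$group == "control"] / 4)
  expect_equal(dens_fold, 7, tolerance = 0.25)
})

test_that("brightfield slides plant exact area fractions, reproducibly", {
  bf <- simulate_brightfield(c(dab = 0.10, vina_green = 0.05), seed = 3)
  expect_equal(bf$truth$fraction, c(0.10, 0.05), tolerance = 0.002)
  expect_equal(bf$truth$fraction[1], sum(bf$masks$dab) / length(bf$masks$dab))
  bf2 <- simulate_brightfield(c(dab = 0.10, vina_green = 0.05), seed = 3)
  expect_identical(bf$rgb, bf2$rgb)
  # blank slide
  b0 <- simulate_brightfield(c(dab = 0, vina_green = 0), seed = 1)
  expect_equal(b0$truth$fraction, c(0, 0))
  expect_error(simulate_brightfield(c(0.4, 0.3), seed = 1),
               class = "mastmap_validation_error")
})

test_that("synthetic counts honour mast fraction, outliers and determinism", {
  sim <- simulate_counts(n_cells = 3000, seed = 11)
  expect_equal(sum(sim$truth$is_mast), 3000 * 0.05, tolerance = 0.25)
  # planted shallow cells fail QC through the gene floor
  met <- qc_metrics(sim$counts)
  shallow <- sim$truth$outlier == "shallow"
  expect_true(all(met$n_genes[shallow] < 1000))
  expect_true(all(!met$passes[shallow]))
  sim2 <- simulate_counts(n_cells = 3000, seed = 11)
  expect_identical(as.matrix(sim2$counts$counts), as.matrix(sim$counts$counts))
})
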