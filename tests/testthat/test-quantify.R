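test_that("tissue mask covers bright-nuclei frames and rejects empty ones", {
  img <- toy_image(h = 40, w = 50, nuclei = 200, pixel_size_um = 2)
  tis <- tissue_mask(img, study_config())
  expect_true(all(tis))
  expect_equal(attr(tis, "area_mm2"), 40 * 50 * 4 / 1e6)
  img0 <- toy_image(nuclei = 0)
  expect_error(tissue_mask(img0, study_config()),
               class = "mastmap_degenerate_error")
})

test_that("tissue area tracks the generated section within 5%", {
  sec <- default_section()
  tis <- tissue_mask(sec$image, study_config())
  expect_equal(attr(tis, "area_mm2"), 4, tolerance = 0.05)
})

test_that("background is the cell-free tissue median", {
  img <- toy_image(h = 30, w = 30, mrna = 7)
  rois <- label_components(matrix(FALSE, 30, 30), img)
  tis <- matrix(TRUE, 30, 30)
  expect_equal(estimate_background(img, "mrna", rois, tis), 7)
  # planted constant background recovered through the full renderer
  sec <- default_section()
  cells <- default_cells()
  expect_equal(unname(attr(cells, "backgrounds")["mrna"]), 40, tolerance = 0.05)
  expect_equal(unname(attr(cells, "backgrounds")["protein"]), 40, tolerance = 0.05)
  # cells covering all tissue -> 0 with a warning
  allmask <- matrix(TRUE, 30, 30)
  rois2 <- label_components(allmask, img)
  expect_warning(bg <- estimate_background(img, "mrna", rois2, tis))
  expect_equal(bg, 0)
})

test_that("per-cell measurement: exact means, floor rule, sum identity", {
  img <- toy_image(h = 20, w = 20, mrna = 50, protein = 80)
  mask <- matrix(FALSE, 20, 20); mask[5:9, 5:6] <- TRUE  # one 10-px ROI
  rois <- label_components(mask, img)
  cells <- suppressMessages(
    measure_cells(img, rois, c(mrna = 10, protein = 100), "p", "s"))
  expect_equal(cells$mrna_raw, 50)
  expect_equal(cells$mrna_corr, 40)
  expect_equal(cells$protein_corr, 0)      # floored at 0
  # mean x area == summed intensity
  px_area <- img$pixel_size_um^2
  expect_equal(cells$mrna_raw * cells$area_um2 / px_area,
               sum(img$channels$mrna[mask]), tolerance = 1e-9)
})

test_that("adding a constant to a channel leaves corrected values unchanged", {
  sec <- default_section()
  cfg <- study_config()
  rois <- suppressMessages(segment_mast_cells(sec$image, cfg))
  tis <- tissue_mask(sec$image, cfg)
  img2 <- sec$image
  img2$channels$mrna <- img2$channels$mrna + 100
  bg1 <- estimate_background(sec$image, "mrna", rois, tis)
  bg2 <- estimate_background(img2, "mrna", rois, tis)
  expect_equal(bg2, bg1 + 100)
  c1 <- suppressMessages(measure_cells(sec$image, rois, c(mrna = bg1, protein = 0)))
  c2 <- suppressMessages(measure_cells(img2, rois, c(mrna = bg2, protein = 0)))
  expect_equal(c2$mrna_corr, c1$mrna_corr, tolerance = 1e-12)
})

test_that("quotients follow the epsilon-regularised ratio", {
  cells <- tibble::tibble(mrna_corr = c(40, 0, 10), protein_corr = c(19, 50, 0))
  out <- compute_quotient(cells, epsilon = 1)
  expect_equal(out$quotient, c(2, 0, 10))
  expect_true(all(is.finite(out$quotient)))
  expect_error(compute_quotient(cells, epsilon = 0),
               class = "mastmap_validation_error")
  expect_error(compute_quotient(cells, epsilon = -1),
               class = "mastmap_validation_error")
})

test_that("gating is strict-greater and monotone in the threshold", {
  cells <- tibble::tibble(mrna_corr = c(299, 300, 301),
                          protein_corr = c(299, 300, 301))
  g <- gate_high(cells, study_config(mrna_high_threshold = 300,
                                     protein_high_threshold = 300))
  expect_identical(g$mrna_high, c(FALSE, FALSE, TRUE)) # at threshold = not high
  # monotone sweep on real measurements
  cm <- default_cells()
  fracs <- vapply(c(100, 200, 300, 500, 800), function(t) {
    mean(gate_high(cm, study_config(mrna_high_threshold = t))$mrna_high)
  }, numeric(1))
  expect_true(all(diff(fracs) <= 0))
})

test_that("compartment assignment uses centroids, innermost-first", {
  ann <- compartment_annotation(
    c("pulmonary_vessel", "airway_epithelium", "airway_subepithelium",
      "alveolar_parenchyma"),
    list(mastmap:::ellipse_polygon(600, 600, 100, 60),
         mastmap:::circle_polygon(200, 200, 60),
         mastmap:::circle_polygon(200, 200, 120),
         rect_poly(0, 0, 800, 800)))
  cells <- tibble::tibble(x_um = c(600, 200, 200, 400, 900),
                          y_um = c(600, 200, 300, 400, 900),
                          compartment = NA_character_)
  out <- assign_compartments(cells, ann)
  expect_equal(out$compartment,
               c("pulmonary_vessel", "airway_epithelium", "airway_subepithelium",
                 "alveolar_parenchyma", "unassigned"))
})

test_that("pipeline cells inherit their planted compartments", {
  sec <- default_section()
  cells <- default_cells()
  m <- match_to_truth(cells, sec$truth, 5)
  agree <- mean(cells$compartment[m$cell_idx] ==
                  sec$truth$compartment[m$truth_idx])
  expect_gte(agree, 0.99)
})

test_that("patient summaries aggregate means, density and fractions", {
  ann <- square_annotation(1000)   # 1 mm^2 parenchyma
  cells <- tibble::tibble(
    cell_id = 1:7, patient_id = "p1", section_id = "s1",
    x_um = seq(100, 700, 100), y_um = 500, area_um2 = 100,
    mean_tryptase = 1000, mrna_raw = 1, protein_raw = 1,
    mrna_corr = c(1, 3, rep(2, 5)), protein_corr = 2,
    quotient = c(1, 3, rep(2, 5)),
    mrna_high = c(TRUE, rep(FALSE, 6)), protein_high = FALSE,
    compartment = "alveolar_parenchyma")
  s <- summarize_patient(cells, ann, group = "control")
  expect_equal(s$n_cells, 7)
  expect_equal(s$mean_quotient, mean(c(1, 3, rep(2, 5))))
  expect_equal(s$density_cells_per_mm2, 7)
  expect_equal(s$frac_mrna_high, 1 / 7)
  # half the area doubles the density: 7 cells in 0.5 mm^2 -> 14 / mm^2
  s2 <- summarize_patient(cells, square_annotation(sqrt(0.5) * 1000), "control")
  expect_equal(s2$density_cells_per_mm2, 14, tolerance = 1e-9)
  # empty compartment reports missing means, zero density
  s3 <- summarize_patient(cells[0, ], ann, "control")
  expect_equal(s3$n_cells, 0)
  expect_true(is.na(s3$mean_mrna_corr))
  expect_equal(s3$density_cells_per_mm2, 0)
})

test_that("measured intensities track planted levels (rank correlation)", {
  sec <- default_section()
  cells <- default_cells()
  m <- match_to_truth(cells, sec$truth, 5)
  expect_gt(length(m$truth_idx), 200)
  r_m <- cor(cells$mrna_corr[m$cell_idx], sec$truth$mrna_true[m$truth_idx],
             method = "spearman")
  r_p <- cor(cells$protein_corr[m$cell_idx], sec$truth$protein_true[m$truth_idx],
             method = "spearman")
  expect_gte(r_m, 0.90)
  expect_gte(r_p, 0.90)
})
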