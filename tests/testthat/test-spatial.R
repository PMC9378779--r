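spatial_cells <- function(n = 300, seed = 1, lo = 400, hi = 1600) {
  set.seed(seed)
  tibble::tibble(x_um = runif(n, lo, hi), y_um = runif(n, lo, hi),
                 quotient = rlnorm(n, 0, 0.3),
                 mrna_corr = rlnorm(n, log(100), 0.3),
                 protein_corr = rlnorm(n, log(100), 0.3))
}

test_that("density maps conserve mass and peak at isolated cells", {
  one <- tibble::tibble(x_um = 500, y_um = 700)
  dm <- density_map(one, grid_um = 50, bandwidth_um = 100,
                    bounds = c(0, 1000, 0, 1000))
  peak <- which(dm$values == max(dm$values), arr.ind = TRUE)
  expect_equal(dm$grid_x[peak[2]], 525, tolerance = 50)
  expect_equal(dm$grid_y[peak[1]], 725, tolerance = 50)
  # mass conservation for interior cells
  cells <- spatial_cells(300)
  dm2 <- density_map(cells, 50, 150, bounds = c(0, 2000, 0, 2000))
  expect_equal(sum(dm2$values), 300, tolerance = 0.02)
  # determinism & empty input
  dm3 <- density_map(cells, 50, 150, bounds = c(0, 2000, 0, 2000))
  expect_identical(dm2$values, dm3$values)
  expect_error(density_map(cells[0, ]), class = "mastmap_degenerate_error")
})

test_that("unweighted value maps reproduce a constant field exactly", {
  cells <- spatial_cells(200)
  cells$quotient <- 5
  vm <- value_map(cells, "quotient", 50, 150, bounds = c(0, 2000, 0, 2000))
  expect_equal(range(vm$values, na.rm = TRUE), c(5, 5))
})

test_that("value maps order planted left/right differences correctly", {
  cells <- spatial_cells(400, seed = 2, lo = 100, hi = 1900)
  cells$quotient <- ifelse(cells$x_um < 1000, 1, 4) * exp(rnorm(400, 0, 0.2))
  vm <- value_map(cells, "quotient", 50, 100, bounds = c(0, 2000, 0, 2000))
  left <- vm$values[, vm$grid_x < 800]
  right <- vm$values[, vm$grid_x > 1200]
  expect_lt(mean(left, na.rm = TRUE), mean(right, na.rm = TRUE))
  # density weighting scales by local mass
  vw <- value_map(cells, "quotient", 50, 100, weighted_by_density = TRUE,
                  bounds = c(0, 2000, 0, 2000))
  expect_false(identical(vm$values, vw$values))
})

test_that("masked no-data fraction grows as the bandwidth shrinks", {
  cells <- spatial_cells(60, seed = 3)
  masked <- vapply(c(300, 150, 60, 30), function(h) {
    vm <- value_map(cells, "quotient", 50, h, bounds = c(0, 2000, 0, 2000))
    mean(is.na(vm$values))
  }, numeric(1))
  expect_true(all(diff(masked) >= 0))
  expect_gt(masked[4], masked[1])
})

test_that("maps are translation-equivariant for grid-aligned shifts", {
  cells <- spatial_cells(150, seed = 4)
  vm <- value_map(cells, "quotient", 50, 150, bounds = c(0, 2000, 0, 2000))
  shifted <- cells
  shifted$x_um <- shifted$x_um + 200   # 4 grid cells
  vs <- value_map(shifted, "quotient", 50, 150, bounds = c(200, 2200, 0, 2000))
  expect_equal(vs$values, vm$values, tolerance = 1e-9)
})

test_that("value maps reject unknown fields", {
  cells <- spatial_cells(50)
  expect_error(value_map(cells, "banana"))
})

test_that("ROI comparisons: null identity, symmetry, contract", {
  set.seed(5)
  base <- tibble::tibble(x_um = runif(50, 0, 900), y_um = runif(50, 0, 900),
                         quotient = rlnorm(50))
  dup <- base; dup$x_um <- dup$x_um + 1000
  cells <- rbind(base, dup)
  roi_a <- rect_poly(0, 0, 950, 950)
  roi_b <- rect_poly(1000, 0, 1950, 950)
  r <- compare_rois(cells, roi_a, roi_b, "quotient")
  expect_equal(r$statistic, 50 * 50 / 2)    # identical multisets: U = n m / 2
  expect_gt(r$p_value, 0.99)
  # label swap flips direction, keeps p
  set.seed(6)
  cells$quotient <- cells$quotient * ifelse(cells$x_um < 1000, 1, 3)
  r1 <- compare_rois(cells, roi_a, roi_b, "quotient")
  r2 <- compare_rois(cells, roi_b, roi_a, "quotient")
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
  expect_equal(unname(r1$statistic + r2$statistic), 50 * 50)
  expect_lt(r1$medians[1], r1$medians[2])
  expect_gt(r2$medians[1], r2$medians[2])
  # too few cells
  expect_error(compare_rois(cells, rect_poly(0, 0, 10, 10), roi_b, "quotient"),
               class = "mastmap_insufficient_data_error")
})

test_that("a planted fourfold quotient contrast is overwhelmingly significant", {
  set.seed(7)
  cells <- tibble::tibble(
    x_um = c(runif(100, 0, 900), runif(100, 1100, 2000)),
    y_um = runif(200, 0, 2000),
    quotient = c(rlnorm(100, log(1), 0.4), rlnorm(100, log(4), 0.4)))
  r <- compare_rois(cells, rect_poly(0, 0, 1000, 2000),
                    rect_poly(1000, 0, 2000, 2000), "quotient")
  expect_lt(r$p_value, 1e-4)
  expect_equal(r$stars, "****")
})
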