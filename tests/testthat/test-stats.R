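test_that("star annotation is a pure threshold map, boundary-exact", {
  p <- c(1, 0.051, 0.05, 0.011, 0.01, 0.0011, 0.001, 0.00011, 1e-4, 1e-5)
  expect_equal(signif_stars(p),
               c("ns", "ns", "*", "*", "**", "**", "***", "***", "****", "****"))
  expect_true(is.na(signif_stars(NA)))
})

test_that("Mann-Whitney matches brute-force enumeration of rank assignments", {
  # {1,2,3} vs {4,5,6}: all 20 assignments of ranks, exact two-sided p
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(r$statistic), 0)
  combos <- utils::combn(6, 3)
  u_null <- apply(combos, 2, function(ix) sum(ix) - 6) # U = ranksum - n(n+1)/2
  p_enum <- mean(u_null <= 0) * 2
  expect_equal(p_enum, 0.1)
  expect_equal(r$p_value, p_enum)
  # random small samples agree with enumeration too
  set.seed(9)
  for (rep in 1:10) {
    a <- sample(100, 4); b <- sample(100, 5)
    while (anyDuplicated(c(a, b))) b <- sample(1000, 5)
    res <- mann_whitney(a, b)
    ranks <- rank(c(a, b))
    u_obs <- sum(ranks[1:4]) - 4 * 5 / 2
    cmb <- utils::combn(9, 4)
    u_all <- apply(cmb, 2, function(ix) sum(ix) - 10)
    p_exact <- min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
    expect_equal(res$p_value, p_exact, tolerance = 1e-12)
  }
})

test_that("Mann-Whitney null identity and contracts", {
  a <- c(5, 7, 9, 11)
  r <- mann_whitney(a, a)
  expect_equal(unname(r$statistic), length(a)^2 / 2)
  expect_gt(r$p_value, 0.99)
  expect_error(mann_whitney(1:2, 1:5),
               class = "mastmap_insufficient_data_error")
})

test_that("Kruskal-Wallis H matches the closed form; Dunn output is coherent", {
  kd <- kruskal_dunn(list(a = 1:3, b = 4:6, c = 7:9))
  # tie-free closed form 12/(N(N+1)) * sum ni (rbar_i - rbar)^2
  h_hand <- 12 / (9 * 10) * 3 * ((2 - 5)^2 + (5 - 5)^2 + (8 - 5)^2)
  expect_equal(kd$h, h_hand)
  expect_equal(kd$h, 7.2)
  expect_equal(nrow(kd$pairwise), 3)
  expect_true(all(kd$pairwise$p_adj >= kd$pairwise$p_raw - 1e-12))
  # three identical groups: H ~ 0, all pairs ns
  kd0 <- kruskal_dunn(list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3)))
  expect_lt(kd0$h, 1e-9)
  expect_true(all(kd0$pairwise$stars == "ns"))
  expect_error(kruskal_dunn(list(a = 1:5, b = 6:10)),
               class = "mastmap_insufficient_data_error")
})

test_that("Dunn z agrees with a permutation null on small groups", {
  set.seed(10)
  g <- list(a = rnorm(4), b = rnorm(4) + 1.5, c = rnorm(4))
  kd <- kruskal_dunn(g, adjust = "none")
  x <- unlist(g); n <- length(x)
  lab <- rep(1:3, each = 4)
  obs <- kd$pairwise$z[kd$pairwise$group_a == "a" & kd$pairwise$group_b == "b"]
  # permutation distribution of the rank-mean difference for pair (a, b)
  stat <- function(l) {
    r <- rank(x)
    mean(r[l == 1]) - mean(r[l == 2])
  }
  obs_d <- stat(lab)
  perm <- replicate(4000, stat(sample(lab)))
  p_perm <- mean(abs(perm) >= abs(obs_d) - 1e-12)
  p_normal <- kd$pairwise$p_raw[kd$pairwise$group_a == "a" &
                                  kd$pairwise$group_b == "b"]
  expect_equal(p_normal, p_perm, tolerance = 0.05)
})

test_that("Spearman matches the rank-difference formula and handles signs", {
  expect_equal(spearman_cor(1:10, 1:10)$r, 1)
  expect_equal(spearman_cor(1:10, 10:1)$r, -1)
  set.seed(11)
  for (rep in 1:10) {
    x <- sample(1000, 12); y <- sample(1000, 12)
    d <- rank(x) - rank(y)
    r_formula <- 1 - 6 * sum(d^2) / (12 * (12^2 - 1))
    expect_equal(spearman_cor(x, y)$r, r_formula, tolerance = 1e-12)
  }
  expect_error(spearman_cor(rep(1, 6), 1:6),
               class = "mastmap_degenerate_error")
  expect_error(spearman_cor(1:4, 4:1),
               class = "mastmap_insufficient_data_error")
})

test_that("capacity fold is the product of expression and density folds", {
  expect_equal(capacity_fold(1, 1), 1)
  expect_equal(capacity_fold(2, 3), 6)
  expect_equal(capacity_fold(4.0, 7.0), 28)
  expect_gte(capacity_fold(4.0, 7.0), 20)
  expect_error(capacity_fold(0, 2), class = "mastmap_validation_error")
  expect_error(capacity_fold(2, -1), class = "mastmap_validation_error")
})

test_that("group tests reject planted patient-level effects with power", {
  # planted 3x effect at study group sizes: patient means, log-normal CV 25%
  set.seed(12)
  rejections <- vapply(1:40, function(i) {
    ctl <- rlnorm(9, log(100), 0.25)
    cop <- rlnorm(10, log(300), 0.25)
    mann_whitney(cop, ctl)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.85)
})
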