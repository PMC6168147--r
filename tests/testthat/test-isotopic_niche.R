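test_that("standard ellipse matches the three-point hand derivation", {
  fit <- fit_standard_ellipse(rbind(c(0, 0), c(1, 0), c(0, 1)))
  expect_equal(unname(fit$cov),
               matrix(c(1 / 3, -1 / 6, -1 / 6, 1 / 3), 2), tolerance = 1e-12)
  expect_equal(fit$sea, pi / sqrt(12), tolerance = 1e-10)
  expect_equal(fit$sea_c, 2 * pi / sqrt(12), tolerance = 1e-10)
  expect_error(fit_standard_ellipse(rbind(c(0, 0), c(1, 1))), "3 points")
  expect_error(fit_standard_ellipse(cbind(1:5, 2 * (1:5))), "singular")
})

test_that("SEA converges to pi for the unit-isotropic normal and SEAc/SEA is (n-1)/(n-2)", {
  set.seed(61)
  big <- fit_standard_ellipse(MASS::mvrnorm(2e5, c(0, 0), diag(2)))
  expect_equal(big$sea, pi, tolerance = 0.02)
  for (n in c(3, 5, 17, 80)) {
    f <- fit_standard_ellipse(MASS::mvrnorm(n, c(0, 0), diag(2)))
    expect_equal(f$sea_c / f$sea, (n - 1) / (n - 2), tolerance = 1e-12)
  }
})

test_that("SEA is rotation invariant and the ellipse rotates with the data", {
  set.seed(62)
  pts <- MASS::mvrnorm(60, c(0, 0), matrix(c(2, 0.8, 0.8, 1), 2))
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  f1 <- fit_standard_ellipse(pts)
  f2 <- fit_standard_ellipse(pts %*% t(R))
  expect_equal(f2$sea, f1$sea, tolerance = 1e-10)
  expect_equal(unname(f2$cov), unname(R %*% f1$cov %*% t(R)), tolerance = 1e-10)
})

test_that("the 1-SD ellipse contains about 39.35% of its own normal scatter", {
  set.seed(63)
  n <- 2e5
  pts <- MASS::mvrnorm(n, c(0, 0), matrix(c(1.5, 0.5, 0.5, 0.8), 2))
  fit <- fit_standard_ellipse(pts)
  ctr <- sweep(pts, 2, fit$centroid)
  md2 <- rowSums((ctr %*% solve(fit$cov)) * ctr)
  cover <- mean(md2 <= 1)
  expect_lt(abs(cover - (1 - exp(-0.5))), 0.005)
})

test_that("Bayesian SEA is seeded, concentrates, and brackets SEAc", {
  set.seed(64)
  pts <- MASS::mvrnorm(5000, c(0, 0), diag(2))
  b1 <- bayesian_sea(pts, n_draws = 2000, seed = 5)
  b2 <- bayesian_sea(pts, n_draws = 2000, seed = 5)
  expect_identical(b1$draws, b2$draws)
  expect_lt(abs(b1$mean - pi) / pi, 0.02)
  # nested central intervals
  expect_lte(b1$intervals["50%", "upper"], b1$intervals["95%", "upper"])
  expect_gte(b1$intervals["50%", "lower"], b1$intervals["95%", "lower"])
  expect_error(bayesian_sea(pts, n_draws = 10), "100 draws")
  # posterior mean area exceeds the ML SEA at small n (small-sample bias
  # direction), converging with n
  set.seed(65)
  small <- MASS::mvrnorm(10, c(0, 0), diag(2))
  bs <- bayesian_sea(small, n_draws = 4000, seed = 2)
  expect_gt(bs$mean, bs$sea_ml)
})

test_that("ellipse overlap agrees with geometry and a Monte-Carlo oracle", {
  f1 <- ellipse_from_cov(c(0, 0), diag(2))
  # identical ellipses: full overlap, significant under the 0.60 rule
  ov <- ellipse_overlap(f1, f1)
  expect_equal(ov$proportion, 1, tolerance = 1e-4)
  expect_true(ov$significant)
  # far-apart ellipses: no overlap
  f3 <- ellipse_from_cov(c(100, 0), diag(2))
  ov3 <- ellipse_overlap(f1, f3)
  expect_equal(ov3$proportion, 0)
  expect_false(ov3$significant)
  # concentric circles with SD 1 and 2: intersection pi, union 4pi -> 0.25
  f2 <- ellipse_from_cov(c(0, 0), 4 * diag(2))
  ov2 <- ellipse_overlap(f1, f2)
  expect_equal(ov2$prop_union, 0.25, tolerance = 1e-3)
  expect_equal(ov2$prop_each1, 1, tolerance = 1e-3)   # small inside big
  # partial overlap of unit circles 1 apart: lens area by closed form
  f4 <- ellipse_from_cov(c(1, 0), diag(2))
  ov4 <- ellipse_overlap(f1, f4)
  lens <- 2 * acos(0.5) - 0.5 * sqrt(3)
  expect_equal(ov4$intersection, lens, tolerance = 1e-3)
  # Monte-Carlo point-membership oracle for the same pair
  set.seed(66)
  u <- cbind(runif(2e5, -1, 2), runif(2e5, -1, 1))
  inside <- rowSums(sweep(u, 2, c(0, 0))^2) <= 1 &
    rowSums(sweep(u, 2, c(1, 0))^2) <= 1
  mc_area <- mean(inside) * 6
  expect_equal(ov4$intersection, mc_area, tolerance = 0.03)
  # symmetry of the union/mean proportions
  ov4r <- ellipse_overlap(f4, f1)
  expect_equal(ov4$prop_union, ov4r$prop_union, tolerance = 1e-9)
  expect_equal(ov4$prop_mean, ov4r$prop_mean, tolerance = 1e-9)
})

test_that("Layman metrics match brute force and handle edge geometry", {
  # two symmetric points
  lm2 <- layman_metrics(rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(lm2$cd, 1)
  expect_equal(unname(c(lm2$cr, lm2$nr, lm2$sr)), c(2, 0, 0))
  # all identical points
  lm0 <- layman_metrics(matrix(1, 4, 3))
  expect_equal(unname(c(lm0$cd, lm0$cr, lm0$nr, lm0$sr)), rep(0, 4))
  # random cloud vs explicit loop oracle (2-D CD)
  set.seed(71)
  pts <- matrix(rnorm(90), 30, 3)
  got <- layman_metrics(pts)
  ctr <- colMeans(pts[, 1:2])
  cd_oracle <- mean(vapply(1:30, function(i) {
    sqrt(sum((pts[i, 1:2] - ctr)^2))
  }, numeric(1)))
  expect_equal(got$cd, cd_oracle, tolerance = 1e-12)
  # 3-axis CD option
  got3 <- layman_metrics(pts, cd_axes = 3)
  ctr3 <- colMeans(pts)
  cd3 <- mean(sqrt(rowSums(sweep(pts, 2, ctr3)^2)))
  expect_equal(got3$cd, cd3, tolerance = 1e-12)
  expect_error(layman_metrics(matrix(1, 1, 3)), "2 points")
})

test_that("bootstrap metrics resample at the smallest group size", {
  set.seed(72)
  pts <- rbind(matrix(rnorm(36), 12, 3), matrix(rnorm(132, 1), 44, 3))
  labels <- rep(c("small", "large"), c(12, 44))
  ci <- bootstrap_metrics(pts, labels, n_boot = 200, seed = 4)
  expect_true(all(ci$resample_size == 12))
  ci2 <- bootstrap_metrics(pts, labels, n_boot = 200, seed = 4)
  expect_identical(ci, ci2)
  expect_true(all(ci$upper >= ci$lower))
  # interval width shrinks as the limiting group grows
  set.seed(73)
  pop <- matrix(rnorm(3000), 1000, 3)
  widths <- vapply(c(10, 100), function(m) {
    sub <- pop[1:m, ]
    ci_m <- bootstrap_metrics(sub, rep("g", m), n_boot = 300, seed = 9)
    mean(ci_m$upper - ci_m$lower)
  }, numeric(1))
  expect_lt(widths[2], widths[1])
})
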