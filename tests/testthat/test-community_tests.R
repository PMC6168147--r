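test_that("pseudo-F agrees with vegan::adonis2 and exact enumeration holds", {
  set.seed(4)
  x <- matrix(abs(rnorm(12 * 5)), 12)
  labels <- rep(c("a", "b", "c"), each = 4)
  D <- as.matrix(vegan::vegdist(x, "bray"))
  res <- permanova_oneway(D, labels, n_perm = 99, seed = 1,
                          exact_threshold = 0)  # force sampled path
  ad <- vegan::adonis2(as.dist(D) ~ labels, permutations = 99)
  expect_equal(res$statistic, ad$F[1], tolerance = 1e-10)
  # small instance: exact p equals a brute-force enumeration oracle
  y <- matrix(abs(rnorm(6 * 3)), 6)
  lab6 <- c("a", "a", "a", "b", "b", "b")
  D6 <- as.matrix(vegan::vegdist(y, "bray"))
  res6 <- permanova_oneway(D6, lab6)
  expect_true(res6$exact)
  # oracle: enumerate all 20 assignments of 3 of 6 rows to group a
  d2 <- D6^2
  fstat <- function(lb) {
    sst <- sum(d2) / (2 * 6)
    ssw <- sum(vapply(split(1:6, lb), function(i) sum(d2[i, i]) / (2 * length(i)),
                      numeric(1)))
    ((sst - ssw) / 1) / (ssw / 4)
  }
  combs <- utils::combn(6, 3)
  f_all <- apply(combs, 2, function(ix) {
    lb <- rep("b", 6); lb[ix] <- "a"; fstat(lb)
  })
  p_oracle <- mean(f_all >= fstat(lab6) - 1e-12)
  expect_equal(res6$p_perm, p_oracle, tolerance = 1e-12)
  expect_equal(res6$unique_perms, 20)
})

test_that("perfectly separated groups reach the minimum attainable p", {
  D <- matrix(1, 4, 4) - diag(4)
  D[1, 2] <- D[2, 1] <- 0; D[3, 4] <- D[4, 3] <- 0
  res <- permanova_oneway(D, c("a", "a", "b", "b"))
  # 6 distinct labelings; the split and its mirror give the same (infinite) F
  expect_true(res$exact)
  expect_equal(res$p_perm, 2 / 6, tolerance = 1e-12)
})

test_that("pairwise t is sqrt(F) and p is invariant to the monotone map", {
  set.seed(8)
  x <- matrix(abs(rnorm(14 * 4)), 14)
  labels <- rep(c("a", "b"), each = 7)
  D <- as.matrix(vegan::vegdist(x, "bray"))
  pr <- pairwise_permanova(D, labels, n_perm = 99, seed = 3,
                           exact_threshold = 0)[["a vs b"]]
  om <- permanova_oneway(D, labels, n_perm = 99, seed = 3,
                         exact_threshold = 0)
  expect_equal(pr$t_statistic^2, om$statistic, tolerance = 1e-10)
  expect_equal(pr$p_perm, om$p_perm)  # same seed, monotone transform
  # near-identical groups: t ~ 0, p ~ 1
  xx <- rbind(x[1:4, ], x[1:4, ])
  DD <- as.matrix(vegan::vegdist(xx, "bray"))
  pr2 <- pairwise_permanova(DD, rep(c("g1", "g2"), each = 4),
                            n_perm = 99, seed = 1)[["g1 vs g2"]]
  expect_lt(pr2$t_statistic, 0.35)
  expect_gt(pr2$p_perm, 0.9)
  expect_error(pairwise_permanova(D, labels, pairs = list(c("a", "zzz"))),
               "missing group")
})

test_that("pseudo-F is invariant to group renaming and row order", {
  set.seed(5)
  x <- matrix(abs(rnorm(12 * 4)), 12)
  labels <- rep(c("a", "b", "c"), each = 4)
  D <- as.matrix(vegan::vegdist(x, "bray"))
  f1 <- permanova_oneway(D, labels, n_perm = 9, seed = 1)$statistic
  f2 <- permanova_oneway(D, c(a = "x", b = "y", c = "z")[labels],
                         n_perm = 9, seed = 1)$statistic
  ord <- sample(12)
  f3 <- permanova_oneway(D[ord, ord], labels[ord], n_perm = 9, seed = 1)$statistic
  expect_equal(f1, f2)
  expect_equal(f1, f3, tolerance = 1e-12)
})

test_that("SIMPER contributions are additive and match vegan", {
  set.seed(6)
  X <- matrix(abs(rnorm(10 * 5)), 10,
              dimnames = list(NULL, paste0("v", 1:5)))
  labels <- rep(c("a", "b"), each = 5)
  sim <- simper_pairwise(X, labels, c("a", "b"))
  expect_equal(sum(sim$contributions$average), sim$overall, tolerance = 1e-6)
  # overall equals the mean cross-pair Bray-Curtis (x100)
  D <- as.matrix(vegan::vegdist(X, "bray"))
  expect_equal(sim$overall, 100 * mean(D[1:5, 6:10]), tolerance = 1e-9)
  vg <- vegan::simper(X, labels)[["a_b"]]
  expect_equal(unname(sort(sim$contributions$average, decreasing = TRUE)),
               unname(sort(100 * vg$average, decreasing = TRUE)),
               tolerance = 1e-6)
  # all guts identical: zero everywhere
  X2 <- matrix(rep(c(2, 1, 3), each = 6), 6)
  sim2 <- simper_pairwise(X2, rep(c("a", "b"), each = 3), c("a", "b"))
  expect_equal(sim2$overall, 0)
  # one-vs-one guts differing in a single variable: it takes 100%
  X3 <- rbind(c(1, 1, 0), c(1, 1, 5))
  sim3 <- simper_pairwise(X3, c("a", "b"), c("a", "b"))
  expect_equal(sim3$contributions$pct_of_total[1], 100)
  expect_error(simper_pairwise(X, labels, c("a", "zzz")), "empty group")
})
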