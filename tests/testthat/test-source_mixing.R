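test_that("posterior draws live on the simplex and anticorrelate exactly", {
  set.seed(81)
  y <- simulate_consumers(30, 0.6, toy_sources())
  post <- fit_two_source_model(y, toy_sources(), steps = 1,
                               iterations = 3000, burn_in = 1500,
                               chains = 2, seed = 7)
  expect_true(all(post$p_pom + post$p_bma == 1))
  expect_true(all(post$p_pom >= 0 & post$p_pom <= 1))
  sm <- summarize_posterior(post, force = TRUE)
  expect_equal(sm$correlation, -1)
  expect_equal(sm$table$mean[1] + sm$table$mean[2], 1, tolerance = 1e-12)
  # reproducible under seed
  post2 <- fit_two_source_model(y, toy_sources(), steps = 1,
                                iterations = 3000, burn_in = 1500,
                                chains = 2, seed = 7)
  expect_identical(post$p_pom, post2$p_pom)
})

test_that("boundary consumers push the posterior to the matching source", {
  set.seed(82)
  src <- toy_sources()
  tdf <- trophic_discrimination()
  y <- cbind(rnorm(20, src$mean_d13c[1] + tdf$mean["d13c"], 0.05),
             rnorm(20, src$mean_d15n[1] + tdf$mean["d15n"], 0.05))
  post <- fit_two_source_model(y, src, steps = 1, iterations = 4000,
                               burn_in = 2000, chains = 2, seed = 3)
  expect_gt(mean(post$p_pom), 0.95)
})

test_that("posterior mean agrees with the closed-form one-isotope solution", {
  # noise-free consumers at the exact mixture mean: p has an algebraic answer
  src <- toy_sources()
  p_true <- 0.65  # BMA share
  mu_c <- (1 - p_true) * src$mean_d13c[1] + p_true * src$mean_d13c[2] + 1.3
  p_closed <- (mu_c - src$mean_d13c[1] - 1.3) /
    (src$mean_d13c[2] - src$mean_d13c[1])
  expect_equal(p_closed, p_true, tolerance = 1e-12)
  set.seed(83)
  y <- simulate_consumers(60, p_true, src, resid_sd = c(0.2, 0.3))
  post <- fit_two_source_model(y, src, steps = 1, iterations = 6000,
                               burn_in = 3000, chains = 3, seed = 17)
  expect_lt(abs(mean(post$p_bma) - p_closed), 0.07)
})

test_that("posterior is symmetric under source relabeling", {
  set.seed(84)
  src <- toy_sources()
  y <- simulate_consumers(40, 0.7, src)
  post <- fit_two_source_model(y, src, steps = 1, iterations = 4000,
                               burn_in = 2000, chains = 2, seed = 5)
  swapped <- src
  swapped$source <- c("BMA", "POM")  # POM now carries BMA's parameters
  post_sw <- fit_two_source_model(y, swapped, steps = 1, iterations = 4000,
                                  burn_in = 2000, chains = 2, seed = 5)
  expect_lt(abs(mean(post$p_bma) - mean(post_sw$p_pom)), 0.03)
})

test_that("input validation catches malformed mixing problems", {
  src <- toy_sources()
  y <- simulate_consumers(10, 0.5, src)
  expect_error(fit_two_source_model(y, src, iterations = 100, burn_in = 100),
               "exceed")
  bad <- src; bad$sd_d13c <- c(0, 0.5)
  expect_error(fit_two_source_model(y, bad), "SDs must be > 0")
  expect_error(fit_two_source_model(y[1:2, ], src), "at least 3")
  noPOM <- src; noPOM$source <- c("XXX", "BMA")
  expect_error(fit_two_source_model(y, noPOM), "POM and BMA")
})

test_that("Gelman-Rubin diagnostics separate mixed from divergent chains", {
  set.seed(85)
  base <- rnorm(2000)
  # duplicated chains: R-hat at 1 up to the split correction
  expect_lt(abs(gelman_rubin(list(base, base)) - 1), 0.01)
  # independent stationary chains: close to 1
  expect_lt(gelman_rubin(list(rnorm(5000), rnorm(5000), rnorm(5000))), 1.01)
  # far-apart chains: clearly divergent
  expect_gt(gelman_rubin(list(rnorm(500, 0), rnorm(500, 10))), 3)
  expect_error(gelman_rubin(list(rnorm(100))), "2 chains")
  expect_error(gelman_rubin(list(rnorm(5), rnorm(5))), "too short")
  expect_error(gelman_rubin(list(rnorm(20), rnorm(30))), "equal length")
})

test_that("longer runs do not worsen convergence on a stationary target", {
  set.seed(86)
  y <- simulate_consumers(40, 0.5, toy_sources())
  rhats <- vapply(c(2000, 10000), function(it) {
    max(fit_two_source_model(y, toy_sources(), steps = 1, iterations = it,
                             burn_in = it / 2, chains = 3,
                             seed = 9)$rhat)
  }, numeric(1))
  expect_lt(rhats[2], rhats[1] + 0.05)
  expect_lt(rhats[2], 1.1)
})

test_that("summaries refuse non-converged fits unless forced", {
  set.seed(87)
  y <- simulate_consumers(20, 0.5, toy_sources())
  post <- fit_two_source_model(y, toy_sources(), iterations = 1200,
                               burn_in = 600, chains = 2, seed = 1)
  post$rhat["p_pom"] <- 1.2; post$converged <- FALSE
  expect_error(summarize_posterior(post), "not converged")
  expect_silent(sm <- summarize_posterior(post, force = TRUE))
  # bookkeeping: summary mean equals the raw draw average
  expect_equal(sm$table$mean[1], mean(as.vector(post$p_pom)))
})
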