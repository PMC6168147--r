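# Small in-code fixtures shared across test files.

# two-gut hand-worked example: gut1 has prey A only, gut2 has A and B
two_gut_records <- function() {
  data.frame(
    fish_id = c("f1", "f2", "f2"),
    taxon = c("A sp.", "A sp.", "B sp."),
    family = c("Af", "Af", "Bf"),
    prey_group = c("A", "A", "B"),
    count = c(2L, 1L, 1L),
    dry_weight = c(2, 1, 1),
    content_flag = "identifiable",
    stringsAsFactors = FALSE)
}

two_gut_fish <- function() {
  data.frame(fish_id = c("f1", "f2"),
             species = "red_snapper", region = "east",
             fork_length = c(200, 210), size_class = "juvenile",
             stringsAsFactors = FALSE)
}

# build an ellipse_fit directly from a centroid/covariance (for geometry
# tests where the "sample" is the population)
ellipse_from_cov <- function(centroid, Sigma, n = 1e6) {
  sea <- pi * sqrt(det(Sigma))
  structure(list(n = n, centroid = centroid, cov = Sigma,
                 sea = sea, sea_c = sea * (n - 1) / (n - 2)),
            class = "ellipse_fit")
}

# grid-search ML oracle for the interior Beta shapes (two-stage refinement);
# independent of the optim-based fit path
beta_grid_oracle <- function(x, lo = 0.05, hi = 12, steps = 60, rounds = 3) {
  ll <- function(a, b) sum(stats::dbeta(x, a, b, log = TRUE))
  arng <- brng <- c(lo, hi)
  best <- c(NA, NA)
  for (r in seq_len(rounds)) {
    as <- seq(arng[1], arng[2], length.out = steps)
    bs <- seq(brng[1], brng[2], length.out = steps)
    grid <- outer(as, bs, Vectorize(ll))
    idx <- arrayInd(which.max(grid), dim(grid))
    best <- c(as[idx[1]], bs[idx[2]])
    da <- diff(arng) / steps; db <- diff(brng) / steps
    arng <- c(max(lo / 10, best[1] - 2 * da), best[1] + 2 * da)
    brng <- c(max(lo / 10, best[2] - 2 * db), best[2] + 2 * db)
  }
  best
}

# minimal two-source table at the published producer means
toy_sources <- function(sd13 = 0.45, sd15 = 1.05) {
  data.frame(source = c("POM", "BMA"),
             mean_d13c = c(-22.50, -18.80), mean_d15n = c(6.03, 5.27),
             sd_d13c = sd13, sd_d15n = sd15, stringsAsFactors = FALSE)
}

# simulate consumers from the mixing model's own generative structure
simulate_consumers <- function(n, p_bma, sources, tdf = trophic_discrimination(),
                               steps = 1, resid_sd = c(0.4, 0.6)) {
  p <- c(1 - p_bma, p_bma)  # (POM, BMA)
  mu_c <- sum(p * sources$mean_d13c) + steps * tdf$mean["d13c"]
  mu_n <- sum(p * sources$mean_d15n) + steps * tdf$mean["d15n"]
  v_c <- sum(p^2 * (sources$sd_d13c^2 + steps^2 * tdf$sd["d13c"]^2)) + resid_sd[1]^2
  v_n <- sum(p^2 * (sources$sd_d15n^2 + steps^2 * tdf$sd["d15n"]^2)) + resid_sd[2]^2
  cbind(stats::rnorm(n, mu_c, sqrt(v_c)), stats::rnorm(n, mu_n, sqrt(v_n)))
}
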