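#' Draw per-gut prey-group proportions from a zero/one-inflated Beta
#'
#' The generative model mirrored by [fit_diet_mixture()]: a gut's proportion
#' for a prey group is exactly 0 with probability `pi0` (group absent),
#' exactly 1 with probability `pi1` (gut filled by the group), and otherwise
#' Beta(`alpha`, `beta`) on the open interval.
#'
#' @param pi0,pi1 point masses at 0 and 1; must satisfy `pi0 + pi1 <= 1`.
#' @param alpha,beta positive Beta shape parameters for interior values.
#' @param n number of guts to draw.
#' @param seed integer seed; same seed gives identical draws.
#' @return numeric vector of length `n` with values in \[0, 1\].
#' @export
generate_gut_proportions <- function(pi0, pi1, alpha, beta, n, seed = NULL) {
  if_stop(pi0 < 0 || pi1 < 0 || pi0 + pi1 > 1 + 1e-12,
          "pi0 and pi1 must be non-negative with pi0 + pi1 <= 1")
  if_stop(alpha <= 0 || beta <= 0, "alpha and beta must be > 0")
  if_stop(n < 1, "n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  u <- stats::runif(n)
  w <- numeric(n)
  w[u < pi0] <- 0
  w[u >= pi0 & u < pi0 + pi1] <- 1
  interior <- u >= pi0 + pi1
  n_int <- sum(interior)
  if (n_int > 0) {
    x <- stats::rbeta(n_int, alpha, beta)
    # rbeta can return exact 0/1 by underflow for extreme shapes; keep interior
    eps <- .Machine$double.eps
    w[interior] <- pmin(pmax(x, eps), 1 - eps)
  }
  w
}

#' Draw muscle isotope triples for one group
#'
#' Independent trivariate normal draws (diagonal covariance by default; a
#' full 3x3 covariance may be supplied for tests that need correlated axes).
#'
#' @param group_mean length-3 mean (d13C, d15N, d34S) in per mil.
#' @param group_sd length-3 positive SDs, or a 3x3 covariance via `Sigma`.
#' @param n number of fish.
#' @param seed integer seed.
#' @param Sigma optional full covariance matrix overriding `group_sd`.
#' @return data frame with columns `d13c`, `d15n`, `d34s`.
#' @export
generate_isotope_samples <- function(group_mean, group_sd, n, seed = NULL,
                                     Sigma = NULL) {
  if_stop(n < 1, "n must be >= 1")
  stopifnot(length(group_mean) == 3)
  if (is.null(Sigma)) {
    if_stop(any(group_sd <= 0), "group_sd components must be > 0")
    Sigma <- diag(group_sd^2, 3)
  }
  if (!is.null(seed)) set.seed(seed)
  x <- MASS::mvrnorm(n, mu = group_mean, Sigma = Sigma)
  x <- matrix(x, ncol = 3)
  data.frame(d13c = x[, 1], d15n = x[, 2], d34s = x[, 3])
}

# representative taxa used to fill the descriptive columns of gut records
.taxon_table <- list(
  barnacles = c("Balanus sp.", "Balanidae"),
  bivalves = c("Mytilidae sp.", "Mytilidae"),
  cnidarians = c("Campanulariidae sp.", "Campanulariidae"),
  crabs = c("Xanthidae sp.", "Xanthidae"),
  fish = c("Teleostei sp.", "Teleostei"),
  gastropods = c("Cavolinidae sp.", "Cavolinidae"),
  stomatopods = c("Squilla sp.", "Squillidae")
)

#' Generate a complete synthetic study dataset
#'
#' Emulates the published sampling design cell by cell: for every
#' species x size-class x region cell, `max(n_gut, n_iso)` fish are created;
#' the first `n_iso` receive a muscle isotope triple drawn from the cell's
#' trivariate normal, the first `n_gut` receive identifiable gut contents
#' drawn from the zero/one-inflated Beta proportion model (then converted to
#' dry weights via a lognormal total gut weight), and any isotope-only fish
#' receive excluded-type gut content (bait/chyme or empty) so that
#' [filter_guts()] recovers exactly the designed gut sample sizes. Producer
#' (POM, BMA) samples are drawn from their pooled summaries.
#'
#' Per-gut proportions are drawn independently per prey group and then
#' renormalized to sum to 1 when at least one group is non-zero; all-zero
#' guts are redrawn. Counts are 1 plus a Poisson draw scaled by dry weight so
#' that heavier prey fractions carry more individuals.
#'
#' @param design a [study_design()] object.
#' @param seed integer seed; identical seed reproduces the bundle exactly.
#' @return list of class `dataset_bundle` with data frames `fish`, `guts`,
#'   `isotopes`, `sources`, and a `provenance` list recording the seed.
#' @export
generate_study <- function(design = study_design(), seed = 1L) {
  validate_design(design)
  set.seed(seed)
  cl <- design$cells
  fish_list <- list(); gut_list <- list(); iso_list <- list()
  fish_counter <- 0L
  for (i in seq_len(nrow(cl))) {
    sp <- cl$species[i]; sc <- cl$size_class[i]; rg <- cl$region[i]
    n_gut <- cl$n_gut[i]; n_iso <- cl$n_iso[i]
    n_fish <- max(n_gut, n_iso)
    if (n_fish == 0L) next
    fr <- design$fl_ranges
    fr <- fr[fr$species == sp & fr$size_class == sc, ]
    ids <- sprintf("%s_%s_%s_%03d", substr(sp, 1, 2), substr(rg, 1, 2),
                   substr(sc, 1, 2), fish_counter + seq_len(n_fish))
    fish_counter <- fish_counter + n_fish
    fl <- stats::runif(n_fish, fr$fl_min, fr$fl_max)
    fish_list[[length(fish_list) + 1L]] <- data.frame(
      fish_id = ids, species = sp, region = rg,
      fork_length = fl, size_class = sc, stringsAsFactors = FALSE)
    if (n_iso > 0L) {
      iso <- generate_isotope_samples(
        c(cl$mean_d13c[i], cl$mean_d15n[i], cl$mean_d34s[i]),
        c(cl$sd_d13c[i], cl$sd_d15n[i], cl$sd_d34s[i]), n_iso)
      iso$fish_id <- ids[seq_len(n_iso)]
      iso_list[[length(iso_list) + 1L]] <- iso[, c("fish_id", "d13c", "d15n", "d34s")]
    }
    pp <- design$prey_params
    pp <- pp[pp$species == sp & pp$region == rg, ]
    for (j in seq_len(n_fish)) {
      if (j <= n_gut) {
        gut_list[[length(gut_list) + 1L]] <-
          .draw_one_gut(ids[j], pp, design)
      } else {
        # isotope-only fish: gut excluded from diet analysis by design
        gut_list[[length(gut_list) + 1L]] <- data.frame(
          fish_id = ids[j], taxon = "Scomber scombrus", family = "Scombridae",
          prey_group = NA_character_, count = 1L,
          dry_weight = stats::rlnorm(1, -2, 0.5),
          content_flag = sample(c("bait", "chyme"), 1),
          stringsAsFactors = FALSE)
      }
    }
  }
  sources <- .draw_sources(design)
  bundle <- structure(list(
    fish = do.call(rbind, fish_list),
    guts = do.call(rbind, gut_list),
    isotopes = do.call(rbind, iso_list),
    sources = sources,
    provenance = list(seed = seed, generated = "synthetic")
  ), class = "dataset_bundle")
  rownames(bundle$fish) <- rownames(bundle$guts) <-
    rownames(bundle$isotopes) <- NULL
  bundle
}

#' @noRd
.draw_one_gut <- function(fish_id, pp, design) {
  repeat {
    w <- vapply(seq_len(nrow(pp)), function(k) {
      generate_gut_proportions(pp$pi0[k], pp$pi1[k], pp$alpha[k], pp$beta[k],
                               n = 1L)
    }, numeric(1))
    if (any(w > 0)) break  # all-zero guts are regenerated
  }
  w <- w / sum(w)
  keep <- which(w > 0)
  total <- stats::rlnorm(1, design$gut_weight_meanlog, design$gut_weight_sdlog)
  dw <- w[keep] * total
  counts <- 1L + stats::rpois(length(keep), 5 * dw)
  tax <- .taxon_table[pp$prey_group[keep]]
  data.frame(
    fish_id = fish_id,
    taxon = vapply(tax, `[`, "", 1L),
    family = vapply(tax, `[`, "", 2L),
    prey_group = pp$prey_group[keep],
    count = counts,
    dry_weight = dw,
    content_flag = "identifiable",
    stringsAsFactors = FALSE)
}

#' @noRd
.draw_sources <- function(design) {
  pr <- design$producers
  out <- lapply(seq_len(nrow(pr)), function(i) {
    data.frame(
      sample_id = sprintf("%s_%02d", pr$source[i], seq_len(pr$n[i])),
      source = pr$source[i],
      d13c = stats::rnorm(pr$n[i], pr$mean_d13c[i], pr$sd_d13c[i]),
      d15n = stats::rnorm(pr$n[i], pr$mean_d15n[i], pr$sd_d15n[i]),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
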