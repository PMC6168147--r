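#' Maximum-likelihood standard ellipse of a bivariate isotope scatter
#'
#' Centroid and sample covariance (denominator n - 1) of (d13C, d15N)
#' points; the standard ellipse is the 1-SD Mahalanobis contour, which for
#' bivariate normal data contains 1 - exp(-1/2), about 40%, of the
#' distribution. SEA = pi * sqrt(det(cov)); the small-sample corrected area
#' is SEAc = SEA * (n - 1) / (n - 2).
#'
#' @param points two-column matrix or data frame of (d13C, d15N) pairs,
#'   n >= 3.
#' @return object of class `ellipse_fit`: `n`, `centroid`, `cov`, `sea`,
#'   `sea_c`.
#' @export
fit_standard_ellipse <- function(points) {
  pts <- as.matrix(points)
  if_stop(ncol(pts) != 2, "points must have two columns")
  n <- nrow(pts)
  if_stop(n < 3, "need at least 3 points")
  ctr <- colMeans(pts)
  S <- stats::cov(pts)
  dt <- det(S)
  if_stop(!is.finite(dt) || dt <= 0, "singular covariance (degenerate scatter)")
  sea <- pi * sqrt(dt)
  structure(list(n = n, centroid = ctr, cov = S,
                 sea = sea, sea_c = sea * (n - 1) / (n - 2)),
            class = "ellipse_fit")
}

#' @export
print.ellipse_fit <- function(x, ...) {
  cat(sprintf("standard ellipse: n = %d, SEA = %.4f, SEAc = %.4f (per mil^2)\n",
              x$n, x$sea, x$sea_c))
  invisible(x)
}

#' Polygonal boundary of a fitted ellipse
#'
#' Vertices of the ellipse whose area equals `sea_c` (default) or `sea`,
#' i.e. the 1-SD covariance contour, optionally rescaled by the
#' small-sample correction.
#'
#' @param fit an [fit_standard_ellipse()] object.
#' @param n_vertices number of boundary vertices (default 512).
#' @param corrected use the SEAc scaling (default TRUE).
#' @return `n_vertices` x 2 matrix of boundary points.
#' @export
ellipse_boundary <- function(fit, n_vertices = 512L, corrected = TRUE) {
  theta <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  circ <- rbind(cos(theta), sin(theta))
  L <- t(chol(fit$cov))
  scale <- if (corrected) sqrt((fit$n - 1) / (fit$n - 2)) else 1
  t(fit$centroid + scale * (L %*% circ))
}

# Sutherland-Hodgman clipping of a convex subject polygon by a convex clip
# polygon (both counter-clockwise). Returns the intersection polygon.
.clip_convex <- function(subject, clip) {
  out <- subject
  nc <- nrow(clip)
  for (e in seq_len(nc)) {
    if (nrow(out) == 0) return(out)
    a <- clip[e, ]; b <- clip[if (e == nc) 1L else e + 1L, ]
    ex <- b[1] - a[1]; ey <- b[2] - a[2]
    inside <- function(p) ex * (p[2] - a[2]) - ey * (p[1] - a[1]) >= 0
    inp <- out
    out <- matrix(numeric(0), ncol = 2)
    np <- nrow(inp)
    for (i in seq_len(np)) {
      p <- inp[i, ]; q <- inp[if (i == np) 1L else i + 1L, ]
      pin <- inside(p); qin <- inside(q)
      if (pin && qin) {
        out <- rbind(out, q)
      } else if (pin && !qin) {
        out <- rbind(out, .seg_line_intersect(p, q, a, b))
      } else if (!pin && qin) {
        out <- rbind(out, .seg_line_intersect(p, q, a, b), q)
      }
    }
  }
  out
}

.seg_line_intersect <- function(p, q, a, b) {
  d1 <- q - p; d2 <- b - a
  denom <- d1[1] * d2[2] - d1[2] * d2[1]
  t <- ((a[1] - p[1]) * d2[2] - (a[2] - p[2]) * d2[1]) / denom
  p + t * d1
}

.polygon_area <- function(poly) {
  if (is.null(nrow(poly)) || nrow(poly) < 3) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Overlap between two corrected standard ellipses
#'
#' Intersection area of the two SEAc ellipses by polygonal approximation
#' (>= 512 vertices each) with exact convex-polygon clipping. The overlap
#' proportion uses the `union` denominator by default
#' (intersection / (A1 + A2 - intersection)); `mean` and the two
#' single-ellipse ratios are reported alongside. Overlap is flagged
#' significant when the proportion reaches `threshold` (default 0.60).
#'
#' @param fit1,fit2 [fit_standard_ellipse()] objects.
#' @param denominator convention driving `proportion` and the flag.
#' @param threshold significance cutoff on the proportion (default 0.60).
#' @param n_vertices boundary vertices per ellipse (default 512).
#' @return list of class `overlap_result`: `intersection` (per mil^2),
#'   `proportion`, `significant`, plus `prop_union`, `prop_mean`,
#'   `prop_each1`, `prop_each2` and the two SEAc areas.
#' @export
ellipse_overlap <- function(fit1, fit2,
                            denominator = c("union", "mean", "each"),
                            threshold = 0.60, n_vertices = 512L) {
  denominator <- match.arg(denominator)
  a1 <- fit1$sea_c; a2 <- fit2$sea_c
  if_stop(!is.finite(a1) || !is.finite(a2) || a1 <= 0 || a2 <= 0,
          "degenerate ellipse")
  p1 <- ellipse_boundary(fit1, n_vertices)
  p2 <- ellipse_boundary(fit2, n_vertices)
  inter <- .polygon_area(.clip_convex(p1, p2))
  inter <- min(inter, a1, a2)
  props <- c(union = inter / (a1 + a2 - inter),
             mean = inter / ((a1 + a2) / 2),
             each1 = inter / a1, each2 = inter / a2)
  prop <- switch(denominator, union = props[["union"]],
                 mean = props[["mean"]],
                 each = min(props[["each1"]], props[["each2"]]))
  structure(list(intersection = inter, proportion = prop,
                 significant = prop >= threshold,
                 prop_union = props[["union"]], prop_mean = props[["mean"]],
                 prop_each1 = props[["each1"]], prop_each2 = props[["each2"]],
                 sea_c1 = a1, sea_c2 = a2, denominator = denominator,
                 threshold = threshold),
            class = "overlap_result")
}

#' Bayesian posterior for the standard ellipse area
#'
#' Conjugate posterior draws of the covariance matrix; the default prior is
#' the vague (Jeffreys) limit, under which the posterior is
#' Inverse-Wishart(n - 1, S) with S the centered sum of squares — this makes
#' the credible interval for the area an exact probability pivot, so
#' coverage of the true SEA is exactly nominal for normal data. A proper
#' normal-inverse-Wishart prior is available through `prior_df` and
#' `prior_scale`. Each draw's area is pi * sqrt(det(Sigma)).
#'
#' @param points (d13C, d15N) pairs, n >= 3.
#' @param n_draws posterior draws (>= 100; default 10^4).
#' @param seed integer seed.
#' @param prior_df additional prior degrees of freedom (0 = vague default).
#' @param prior_scale 2x2 prior scale matrix added to S (0 = vague default).
#' @param probs credible-interval levels (default 50/75/95%).
#' @return list of class `bayesian_sea`: `draws` (areas, per mil^2),
#'   `mean`, `intervals` (matrix of central intervals), `sea_ml`, `sea_c`.
#' @export
bayesian_sea <- function(points, n_draws = 10000L, seed = NULL,
                         prior_df = 0, prior_scale = matrix(0, 2, 2),
                         probs = c(0.50, 0.75, 0.95)) {
  if_stop(n_draws < 100, "need at least 100 draws")
  fit <- fit_standard_ellipse(points)
  n <- fit$n
  S <- fit$cov * (n - 1) + prior_scale
  df <- n - 1 + prior_df
  if (!is.null(seed)) set.seed(seed)
  W <- stats::rWishart(n_draws, df = df, Sigma = solve(S))
  # Sigma = W^{-1} ~ InvWishart(df, S); area = pi * sqrt(det Sigma)
  detW <- W[1, 1, ] * W[2, 2, ] - W[1, 2, ] * W[2, 1, ]
  draws <- pi / sqrt(detW)
  ints <- t(vapply(probs, function(p) {
    stats::quantile(draws, c((1 - p) / 2, 1 - (1 - p) / 2), names = FALSE)
  }, numeric(2)))
  dimnames(ints) <- list(paste0(100 * probs, "%"), c("lower", "upper"))
  structure(list(draws = draws, mean = mean(draws), intervals = ints,
                 sea_ml = fit$sea, sea_c = fit$sea_c, n = n),
            class = "bayesian_sea")
}

#' @export
print.bayesian_sea <- function(x, ...) {
  cat(sprintf("Bayesian SEA: posterior mean %.4f (SEAc %.4f), n = %d\n",
              x$mean, x$sea_c, x$n))
  print(round(x$intervals, 4))
  invisible(x)
}

#' Layman-style niche metrics
#'
#' CD is the mean Euclidean distance of points to their centroid in the
#' d13C-d15N plane (optionally in all three axes); CR, NR and SR are the
#' max - min ranges of d13C, d15N and d34S.
#'
#' @param points matrix or data frame with columns (d13C, d15N, d34S),
#'   n >= 2.
#' @param cd_axes 2 (default; d13C-d15N plane, matching the 2-D ellipse
#'   analyses) or 3 to include d34S in CD.
#' @return list with `cd`, `cr`, `nr`, `sr`, `n`.
#' @export
layman_metrics <- function(points, cd_axes = 2) {
  pts <- as.matrix(points)
  if_stop(ncol(pts) != 3, "points must have three columns (d13C, d15N, d34S)")
  if_stop(nrow(pts) < 2, "need at least 2 points")
  stopifnot(cd_axes %in% c(2, 3))
  sub <- pts[, seq_len(cd_axes), drop = FALSE]
  ctr <- colMeans(sub)
  cd <- mean(sqrt(rowSums(sweep(sub, 2, ctr)^2)))
  rng <- apply(pts, 2, function(v) diff(range(v)))
  list(cd = cd, cr = rng[1], nr = rng[2], sr = rng[3], n = nrow(pts))
}

#' Bootstrap confidence intervals for niche metrics across groups
#'
#' Because group sample sizes are unbalanced, every bootstrap replicate
#' resamples (with replacement) exactly m points per group, where m is the
#' smallest group size, so widths are comparable across groups. Percentile
#' intervals are reported.
#'
#' @param points matrix/data frame of (d13C, d15N, d34S) triples.
#' @param labels group label per row (each group n >= 2).
#' @param n_boot bootstrap replicates (default 10000).
#' @param seed integer seed.
#' @param level confidence level (default 0.95).
#' @param cd_axes passed to [layman_metrics()].
#' @return data frame with one row per group x metric: `group`, `metric`,
#'   `estimate`, `boot_mean`, `lower`, `upper`, `resample_size`.
#' @export
bootstrap_metrics <- function(points, labels, n_boot = 10000L, seed = NULL,
                              level = 0.95, cd_axes = 2) {
  pts <- as.matrix(points)
  tab <- table(labels)
  m <- min(tab)
  if_stop(m < 2, "smallest group has n < 2")
  if (!is.null(seed)) set.seed(seed)
  alpha <- (1 - level) / 2
  out <- list()
  for (g in names(tab)) {
    sub <- pts[labels == g, , drop = FALSE]
    est <- layman_metrics(sub, cd_axes)
    boots <- matrix(NA_real_, n_boot, 4)
    for (b in seq_len(n_boot)) {
      bs <- sub[sample.int(nrow(sub), m, replace = TRUE), , drop = FALSE]
      lm_ <- layman_metrics(bs, cd_axes)
      boots[b, ] <- c(lm_$cd, lm_$cr, lm_$nr, lm_$sr)
    }
    for (j in seq_len(4)) {
      metric <- c("cd", "cr", "nr", "sr")[j]
      qs <- stats::quantile(boots[, j], c(alpha, 1 - alpha), names = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        group = g, metric = metric,
        estimate = unname(c(est$cd, est$cr, est$nr, est$sr)[j]),
        boot_mean = mean(boots[, j]),
        lower = qs[1], upper = qs[2], resample_size = m,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
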