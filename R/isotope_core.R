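#' Convert an isotope ratio to delta notation
#'
#' delta = (R_sample / R_standard - 1) x 1000, in per mil relative to the
#' international standard (VPDB for carbon, atmospheric N2 for nitrogen,
#' VCDT for sulfur).
#'
#' @param R_sample heavy/light isotope ratio of the sample.
#' @param R_standard heavy/light ratio of the standard (> 0).
#' @return delta value(s), per mil.
#' @export
ratio_to_delta <- function(R_sample, R_standard) {
  if_stop(any(R_standard <= 0), "R_standard must be > 0")
  (R_sample / R_standard - 1) * 1000
}

#' Pooled primary-producer baseline d15N
#'
#' Sample-size-weighted mean of the POM and BMA d15N means, the baseline for
#' trophic-level estimation when producer values are pooled across regions.
#'
#' @param producers data frame with columns `source`, `mean_d15n`, `n`
#'   (as in [study_design()]`$producers`).
#' @return pooled mean d15N, per mil.
#' @export
pooled_producer_d15n <- function(producers) {
  stopifnot(all(c("mean_d15n", "n") %in% names(producers)))
  sum(producers$mean_d15n * producers$n) / sum(producers$n)
}

#' Post trophic-level estimate
#'
#' TL = 1 + (d15N_fish - d15N_prod) / Delta_n, where d15N_prod is the pooled
#' producer baseline and Delta_n the per-step trophic discrimination factor.
#'
#' @param d15n_fish consumer d15N value(s), per mil.
#' @param d15n_prod producer baseline d15N, per mil.
#' @param delta_n trophic discrimination factor per trophic level
#'   (default 3.4 per mil).
#' @return numeric trophic level(s).
#' @export
trophic_level <- function(d15n_fish, d15n_prod, delta_n = 3.4) {
  if_stop(delta_n <= 0, "delta_n must be > 0")
  1 + (d15n_fish - d15n_prod) / delta_n
}

#' Length-adjust isotope values
#'
#' Removes the linear relationship between an isotope axis and body size:
#' dX' = dX - a * FL. With `a = "fit"` the coefficient is the ordinary
#' least-squares slope of dX on FL over the supplied set, so adjusted values
#' have zero OLS slope on FL.
#'
#' @param values isotope values, per mil.
#' @param FL fork lengths, mm.
#' @param a regression coefficient (per mil per mm) or `"fit"`.
#' @return list with `adjusted` values and the coefficient `a` used.
#' @export
length_adjust <- function(values, FL, a = "fit") {
  if_stop(length(values) != length(FL), "values and FL must have equal length")
  if (identical(a, "fit")) {
    if_stop(length(FL) < 3, "need >= 3 points to fit a")
    if_stop(stats::var(FL) <= 0, "zero fork-length variance; cannot fit a")
    a <- unname(stats::coef(stats::lm(values ~ FL))[2])
  }
  list(adjusted = values - a * FL, a = a)
}

#' One-way MANOVA on an isotope matrix
#'
#' Pillai-trace one-way MANOVA with the standard F approximation; in the
#' two-group case the statistic is numerically equivalent to the Hotelling
#' T-squared test.
#'
#' @param Y numeric matrix, rows = individuals, columns = isotope axes.
#' @param labels group labels per row (>= 2 groups).
#' @return list with `pillai`, `f`, `df1`, `df2`, `p`.
#' @export
manova_test <- function(Y, labels) {
  Y <- as.matrix(Y)
  labels <- factor(labels)
  if_stop(nlevels(labels) < 2, "need at least 2 groups")
  if_stop(nrow(Y) <= nlevels(labels) + ncol(Y),
          "too few observations for the number of groups and axes")
  if (all(apply(Y, 2, stats::var) == 0)) {
    # no variation at all: trivially no group effect
    return(list(pillai = 0, f = 0, df1 = NA_real_, df2 = NA_real_, p = 1))
  }
  resid_rank <- tryCatch(
    qr(stats::resid(stats::lm(Y ~ labels)))$rank, error = function(e) 0)
  if_stop(resid_rank < ncol(Y),
          "singular within-group covariance (collinear isotope axes)")
  fit <- stats::manova(Y ~ labels)
  s <- summary(fit, test = "Pillai")$stats
  list(pillai = s[1, "Pillai"], f = s[1, "approx F"],
       df1 = s[1, "num Df"], df2 = s[1, "den Df"], p = s[1, "Pr(>F)"])
}

# Attainable numbers of true pairwise null hypotheses among k groups
# (Shaffer's logical constraints): S(k) = union over first-block sizes j of
# choose(j, 2) + S(k - j).
.shaffer_true_counts <- function(k) {
  memo <- list("0" = 0L, "1" = 0L)
  rec <- function(k) {
    key <- as.character(k)
    if (!is.null(memo[[key]])) return(memo[[key]])
    vals <- integer(0)
    for (j in seq_len(k)) {
      vals <- c(vals, choose(j, 2) + rec(k - j))
    }
    res <- sort(unique(as.integer(vals)))
    memo[[key]] <<- res
    res
  }
  rec(k)
}

#' Shaffer's multiple comparison procedure over all pairwise means
#'
#' All-pairs Welch (unequal-variance) t tests followed by Shaffer's
#' modified-Bonferroni step-down: sorted p-values p_(i) are tested against
#' alpha / t_i, where t_i is the largest number of pairwise null hypotheses
#' that can simultaneously be true once i - 1 have been rejected (for k = 3
#' groups the sequence is 3, 1, 1). Testing stops at the first
#' non-rejection, so decisions are monotone. Less conservative than
#' Bonferroni yet robust to unbalanced sample sizes.
#'
#' @param values numeric response vector.
#' @param labels group labels (each group n >= 2).
#' @param alpha family-wise error level (default 0.05).
#' @return data frame with one row per pair: `group1`, `group2`, `t`, `df`,
#'   `p_raw`, `threshold`, `reject`.
#' @export
shaffer_pairwise <- function(values, labels, alpha = 0.05) {
  labels <- as.character(labels)
  tab <- table(labels)
  if_stop(length(tab) < 2, "need at least 2 groups")
  if_stop(any(tab < 2), paste("group with n < 2:",
                              paste(names(tab)[tab < 2], collapse = ", ")))
  k <- length(tab)
  prs <- utils::combn(names(tab), 2, simplify = FALSE)
  res <- do.call(rbind, lapply(prs, function(pr) {
    tt <- stats::t.test(values[labels == pr[1]], values[labels == pr[2]],
                        var.equal = FALSE)
    data.frame(group1 = pr[1], group2 = pr[2],
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_raw = tt$p.value, stringsAsFactors = FALSE)
  }))
  m <- nrow(res)
  counts <- .shaffer_true_counts(k)
  ord <- order(res$p_raw)
  t_seq <- vapply(seq_len(m), function(i) {
    cand <- counts[counts <= m - i + 1 & counts >= 1]
    if (length(cand) == 0) 1L else max(cand)
  }, numeric(1))
  thresholds <- alpha / t_seq
  reject_sorted <- logical(m)
  for (i in seq_len(m)) {
    if (res$p_raw[ord[i]] <= thresholds[i]) reject_sorted[i] <- TRUE
    else break  # step-down: stop at first non-rejection
  }
  res$threshold <- NA_real_
  res$threshold[ord] <- thresholds
  res$reject <- FALSE
  res$reject[ord] <- reject_sorted
  res
}

#' Group means and standard errors of isotope values
#'
#' Convenience summary in the shape of a published isotope table: mean and
#' SE per grouping cell for each isotope axis.
#'
#' @param iso data frame with `d13c`, `d15n`, `d34s` columns.
#' @param cells character vector assigning each row to a cell.
#' @return data frame with `cell`, `n`, and `mean_*` / `se_*` columns.
#' @export
isotope_group_summary <- function(iso, cells) {
  stopifnot(nrow(iso) == length(cells))
  out <- lapply(unique(cells), function(cl) {
    sub <- iso[cells == cl, c("d13c", "d15n", "d34s"), drop = FALSE]
    n <- nrow(sub)
    mns <- colMeans(sub)
    ses <- apply(sub, 2, stats::sd) / sqrt(n)
    data.frame(cell = cl, n = n,
               mean_d13c = mns[1], se_d13c = ses[1],
               mean_d15n = mns[2], se_d15n = ses[2],
               mean_d34s = mns[3], se_d34s = ses[3],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
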