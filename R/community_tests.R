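# Permutational multivariate tests on a dissimilarity matrix.

# sum of squares partition from squared dissimilarities (Gower identity):
# SS_total = sum_{i<j} d_ij^2 / N ; SS_within = sum_g sum_{i<j in g} d^2 / n_g
.pseudo_f <- function(d2, labels) {
  n <- nrow(d2)
  groups <- split(seq_len(n), labels)
  k <- length(groups)
  ss_tot <- sum(d2) / (2 * n)
  ss_w <- sum(vapply(groups, function(idx) {
    sum(d2[idx, idx]) / (2 * length(idx))
  }, numeric(1)))
  ss_b <- ss_tot - ss_w
  (ss_b / (k - 1)) / (ss_w / (n - k))
}

# all distinct arrangements of a label multiset, as a matrix (rows = labels)
.enumerate_labelings <- function(labels) {
  labs <- sort(unique(labels))
  counts <- as.integer(table(factor(labels, levels = labs)))
  n <- length(labels)
  rec <- function(remaining) {
    nn <- sum(remaining)
    if (nn == 0) return(matrix(integer(0), nrow = 0, ncol = 0))
    if (nn == 1) return(matrix(which(remaining > 0), nrow = 1))
    out <- list()
    for (j in seq_along(remaining)) {
      if (remaining[j] == 0) next
      rem <- remaining; rem[j] <- rem[j] - 1L
      sub <- rec(rem)
      out[[length(out) + 1L]] <- cbind(j, sub)
    }
    do.call(rbind, out)
  }
  m <- rec(counts)
  matrix(labs[m], nrow = nrow(m))
}

.n_distinct_labelings <- function(labels) {
  counts <- table(labels)
  exp(lgamma(length(labels) + 1) - sum(lgamma(counts + 1)))
}

#' One-way PERMANOVA on a dissimilarity matrix
#'
#' Pseudo-F from the squared-dissimilarity partition of total and
#' within-group sums of squares; the p-value comes from random relabeling of
#' the rows, using the (1 + count)/(1 + B) estimator so p is never zero.
#' When the space of distinct label arrangements has at most
#' `exact_threshold` members the full enumeration is used instead and the
#' p-value is exact.
#'
#' @param D square symmetric dissimilarity matrix.
#' @param labels group labels, one per row of `D`; every group needs >= 2
#'   members.
#' @param n_perm number of random relabelings (default 999).
#' @param seed integer seed for the permutations.
#' @param exact_threshold enumerate exactly when the number of distinct
#'   arrangements is at most this (default 10000).
#' @return list of class `permanova_result`: `statistic` (pseudo-F),
#'   `p_perm`, `n_perm`, `unique_perms` (distinct arrangements realized),
#'   `exact`, `df`, `seed`.
#' @export
permanova_oneway <- function(D, labels, n_perm = 999L, seed = NULL,
                             exact_threshold = 10000) {
  D <- as.matrix(D)
  if_stop(nrow(D) != ncol(D) || max(abs(D - t(D))) > 1e-8,
          "D must be square and symmetric")
  if_stop(length(labels) != nrow(D), "labels must align with D")
  tab <- table(labels)
  if_stop(length(tab) < 2, "need at least 2 groups")
  if_stop(any(tab < 2), paste("group of size < 2:",
                              paste(names(tab)[tab < 2], collapse = ", ")))
  d2 <- D^2
  f_obs <- .pseudo_f(d2, labels)
  n <- nrow(D)
  k <- length(tab)
  if (.n_distinct_labelings(labels) <= exact_threshold) {
    all_lab <- .enumerate_labelings(labels)
    f_all <- apply(all_lab, 1, function(lb) .pseudo_f(d2, lb))
    p <- sum(f_all >= f_obs - 1e-12) / length(f_all)
    unique_perms <- nrow(all_lab)
    exact <- TRUE
    n_used <- nrow(all_lab)
  } else {
    if (!is.null(seed)) set.seed(seed)
    perm_keys <- character(n_perm)
    count <- 0L
    for (b in seq_len(n_perm)) {
      lb <- sample(labels)
      perm_keys[b] <- paste(lb, collapse = "\r")
      if (.pseudo_f(d2, lb) >= f_obs - 1e-12) count <- count + 1L
    }
    p <- (1 + count) / (1 + n_perm)
    unique_perms <- length(unique(perm_keys))
    exact <- FALSE
    n_used <- n_perm
  }
  structure(list(statistic = f_obs, p_perm = p, n_perm = n_used,
                 unique_perms = unique_perms, exact = exact,
                 df = c(between = k - 1, within = n - k),
                 seed = seed),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  stat_name <- if (!is.null(x$t_statistic)) "t" else "pseudo-F"
  stat <- if (!is.null(x$t_statistic)) x$t_statistic else x$statistic
  cat(sprintf("PERMANOVA: %s = %.4f, p = %.4g (%s, %d unique perms)\n",
              stat_name, stat, x$p_perm,
              if (x$exact) "exact" else sprintf("%d perms", x$n_perm),
              x$unique_perms))
  invisible(x)
}

#' Pairwise a-posteriori PERMANOVA tests
#'
#' For each requested pair of groups, restricts the matrix to the two groups
#' and reports t = sqrt(two-group pseudo-F) with its permutation p-value
#' (identical to the F permutation p, since the map is monotone).
#'
#' @param D,labels as in [permanova_oneway()].
#' @param pairs list of length-2 character vectors, or `"all"` (default).
#' @param n_perm,seed,exact_threshold as in [permanova_oneway()].
#' @return list of `permanova_result` objects (with `t_statistic` set),
#'   named "A vs B".
#' @export
pairwise_permanova <- function(D, labels, pairs = "all", n_perm = 999L,
                               seed = NULL, exact_threshold = 10000) {
  D <- as.matrix(D)
  labs <- unique(labels)
  if (identical(pairs, "all")) {
    pairs <- utils::combn(labs, 2, simplify = FALSE)
  }
  out <- list()
  for (pr in pairs) {
    if_stop(!all(pr %in% labels),
            paste("pair references missing group:", paste(pr, collapse = ", ")))
    idx <- which(labels %in% pr)
    res <- permanova_oneway(D[idx, idx, drop = FALSE], labels[idx],
                            n_perm = n_perm, seed = seed,
                            exact_threshold = exact_threshold)
    res$t_statistic <- sqrt(res$statistic)
    res$comparison <- paste(pr, collapse = " vs ")
    out[[res$comparison]] <- res
  }
  out
}

#' SIMPER decomposition of between-group dissimilarity
#'
#' For every cross-group pair of rows (i, j), the Bray-Curtis dissimilarity
#' decomposes additively over variables as
#' delta_g(i, j) = 100 |x_ig - x_jg| / sum_h (x_ih + x_jh); the per-variable
#' contribution is the mean of delta_g over all cross pairs, and the
#' contributions sum exactly to the overall average between-group
#' dissimilarity (in percent).
#'
#' @param X data matrix (typically square-root transformed %W), rows =
#'   guts, columns = prey groups.
#' @param labels group labels per row.
#' @param pair length-2 character vector naming the two groups.
#' @return list of class `simper_result`: `pair`, `overall` (average
#'   between-group dissimilarity, %), `contributions` (data frame with
#'   `variable`, `average`, `pct_of_total`, `cumulative_pct`, sorted
#'   decreasing).
#' @export
simper_pairwise <- function(X, labels, pair) {
  X <- as.matrix(X)
  stopifnot(length(pair) == 2)
  i1 <- which(labels == pair[1]); i2 <- which(labels == pair[2])
  if_stop(length(i1) == 0 || length(i2) == 0,
          paste("empty group in pair:", paste(pair, collapse = ", ")))
  g <- ncol(X)
  acc <- numeric(g)
  n_pairs <- 0L
  for (i in i1) {
    for (j in i2) {
      denom <- sum(X[i, ] + X[j, ])
      contrib <- if (denom > 0) 100 * abs(X[i, ] - X[j, ]) / denom
                 else numeric(g)
      acc <- acc + contrib
      n_pairs <- n_pairs + 1L
    }
  }
  avg <- acc / n_pairs
  overall <- sum(avg)
  ord <- order(-avg)
  contributions <- data.frame(
    variable = colnames(X)[ord] %||% as.character(ord),
    average = avg[ord],
    pct_of_total = if (overall > 0) 100 * avg[ord] / overall else 0 * avg[ord],
    stringsAsFactors = FALSE)
  contributions$cumulative_pct <- cumsum(contributions$pct_of_total)
  structure(list(pair = pair, overall = overall,
                 contributions = contributions, n_pairs = n_pairs),
            class = "simper_result")
}

#' @export
print.simper_result <- function(x, ...) {
  cat(sprintf("SIMPER %s vs %s: overall dissimilarity %.2f%%\n",
              x$pair[1], x$pair[2], x$overall))
  print(x$contributions, digits = 4)
  invisible(x)
}
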