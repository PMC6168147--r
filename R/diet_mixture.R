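#' Maximum-likelihood diet mixture estimate for one prey group
#'
#' Fits a zero/one-inflated Beta model to per-gut proportion (%W / 100) data:
#' a gut's proportion is 0 with probability pi0 (prey absent), 1 with
#' probability pi1 (gut filled by the prey), and Beta(alpha, beta) on (0, 1)
#' otherwise. The mean contribution of the prey group to the diet is
#' p = pi1 + (1 - pi0 - pi1) * alpha / (alpha + beta).
#'
#' Point masses have closed-form MLEs (observed fractions of exact zeros and
#' ones); the interior Beta shapes are estimated by numerical maximum
#' likelihood from a method-of-moments start. Model variant selection is
#' deterministic from the data: `absent` when no gut contains the group,
#' `inapplicable` when fewer than `min_nonzero` guts contain it, `full` when
#' at least one gut is 100% this prey, and otherwise `reduced` (pi1 fixed at
#' 0, used when no gut meets the full model's p = 1 assumption). Standard
#' errors come from a nonparametric bootstrap over guts.
#'
#' @param proportions numeric vector in \[0, 1\], one value per gut.
#' @param min_nonzero minimum number of guts containing the prey for the
#'   model to apply (default 3).
#' @param n_boot bootstrap resamples for the SE (0 skips the bootstrap).
#' @param seed integer seed for the bootstrap.
#' @param variant force a variant (`"auto"` default). Requesting `"reduced"`
#'   on data containing an exact 1 is an error: the reduced model assumes no
#'   gut is fully composed of the prey.
#' @return object of class `diet_mixture_fit`: list with `p` (mean
#'   contribution in \[0, 1\]), `se`, `variant`, counts (`n`, `n_zero`,
#'   `n_one`, `n_interior`), fitted `pi0`, `pi1`, `alpha`, `beta`, and
#'   `interior_fallback` (TRUE when the Beta fit fell back to a point mass /
#'   method of moments).
#' @export
fit_diet_mixture <- function(proportions, min_nonzero = 3L, n_boot = 1000L,
                             seed = NULL, variant = c("auto", "full", "reduced")) {
  variant <- match.arg(variant)
  w <- proportions
  if_stop(length(w) < 1, "need at least one gut")
  if_stop(any(!is.finite(w)) || any(w < -1e-9 | w > 1 + 1e-9),
          "proportions must lie in [0, 1]")
  # snap floating-point noise at the boundaries (%W/100 conversions)
  w[w >= 1] <- 1
  w[w <= 0] <- 0
  n <- length(w)
  n_zero <- sum(w == 0); n_one <- sum(w == 1)
  n_nonzero <- n - n_zero
  n_interior <- n - n_zero - n_one
  if (variant == "reduced") {
    if_stop(n_one > 0,
            "reduced model assumes no gut is 100% this prey, but data contain a 1")
  }
  sel <- if (n_nonzero == 0) "absent"
  else if (n_nonzero < min_nonzero) "inapplicable"
  else if (n_one > 0) "full" else "reduced"
  if (variant != "auto" && sel %in% c("full", "reduced")) sel <- variant
  fit <- .fit_zoib(w, sel)
  se <- NA_real_
  if (n_boot > 0 && sel %in% c("full", "reduced")) {
    if (!is.null(seed)) set.seed(seed)
    boot <- vapply(seq_len(n_boot), function(b) {
      wb <- w[sample.int(n, n, replace = TRUE)]
      .fit_zoib(wb, if (any(wb == 1)) "full" else "reduced")$p
    }, numeric(1))
    se <- stats::sd(boot)
  }
  structure(list(
    p = fit$p, se = se, variant = sel,
    n = n, n_zero = n_zero, n_one = n_one, n_interior = n_interior,
    pi0 = fit$pi0, pi1 = fit$pi1, alpha = fit$alpha, beta = fit$beta,
    interior_fallback = fit$fallback
  ), class = "diet_mixture_fit")
}

#' @export
print.diet_mixture_fit <- function(x, ...) {
  mark <- switch(x$variant, reduced = "*", inapplicable = "X",
                 absent = "NA", "")
  cat(sprintf("diet mixture fit [%s%s]: p = %.4f (%.2f%%), SE = %s, n = %d\n",
              x$variant, mark, x$p, 100 * x$p,
              ifelse(is.na(x$se), "NA", sprintf("%.4f", x$se)), x$n))
  invisible(x)
}

# core ML machinery for the zero/one-inflated Beta on one vector
.fit_zoib <- function(w, sel) {
  n <- length(w)
  n_zero <- sum(w == 0); n_one <- sum(w == 1)
  interior <- w[w > 0 & w < 1]
  pi0 <- n_zero / n
  pi1 <- if (identical(sel, "reduced")) 0 else n_one / n
  if (identical(sel, "absent")) {
    return(list(p = 0, pi0 = 1, pi1 = 0, alpha = NA_real_, beta = NA_real_,
                fallback = FALSE))
  }
  if (identical(sel, "inapplicable")) {
    return(list(p = NA_real_, pi0 = pi0, pi1 = pi1, alpha = NA_real_,
                beta = NA_real_, fallback = FALSE))
  }
  if (length(interior) == 0) {
    return(list(p = pi1, pi0 = pi0, pi1 = pi1, alpha = NA_real_,
                beta = NA_real_, fallback = FALSE))
  }
  ab <- .fit_beta_interior(interior)
  mu <- if (ab$fallback) mean(interior) else ab$alpha / (ab$alpha + ab$beta)
  p <- pi1 + (1 - pi0 - pi1) * mu
  list(p = p, pi0 = pi0, pi1 = pi1, alpha = ab$alpha, beta = ab$beta,
       fallback = ab$fallback)
}

# Beta ML on interior values with moment-matched start; sufficient-statistic
# likelihood so cost does not grow with n inside optim.
.fit_beta_interior <- function(x) {
  n <- length(x)
  if (n < 2 || stats::var(x) < 1e-12) {
    # all interior values (numerically) equal: point mass at that value
    return(list(alpha = NA_real_, beta = NA_real_, fallback = TRUE))
  }
  m <- mean(x); v <- stats::var(x)
  # method of moments start (guard against v >= m(1-m))
  c0 <- max(m * (1 - m) / v - 1, 0.1)
  start <- log(c(max(m * c0, 1e-3), max((1 - m) * c0, 1e-3)))
  slx <- sum(log(x)); sl1x <- sum(log1p(-x))
  nll <- function(par) {
    a <- exp(par[1]); b <- exp(par[2])
    if (!is.finite(a) || !is.finite(b) || a > 1e8 || b > 1e8) return(1e10)
    -((a - 1) * slx + (b - 1) * sl1x - n * lbeta(a, b))
  }
  opt <- try(stats::optim(start, nll, method = "Nelder-Mead",
                          control = list(maxit = 500)), silent = TRUE)
  if (inherits(opt, "try-error") || opt$convergence != 0) {
    return(list(alpha = m * c0, beta = (1 - m) * c0, fallback = TRUE))
  }
  list(alpha = exp(opt$par[1]), beta = exp(opt$par[2]), fallback = FALSE)
}

#' Diet-mixture estimates for every prey group within grouping cells
#'
#' Applies [fit_diet_mixture()] to the per-gut %W proportions of each prey
#' group within each cell (e.g. species x size class), producing a table of
#' percent contribution +/- SE with the conventional markers: `*` reduced
#' model, `X` too few guts containing the prey, `NA` prey absent.
#'
#' @param w_matrix guts x prey-groups %W matrix (rows sum to 100).
#' @param cells character vector assigning each gut (row) to a cell.
#' @param min_nonzero,n_boot,seed passed to [fit_diet_mixture()].
#' @return data frame with one row per cell x prey group: `cell`,
#'   `prey_group`, `estimate_pct`, `se_pct`, `variant`, `marker`, `label`.
#' @export
diet_mixture_table <- function(w_matrix, cells, min_nonzero = 3L,
                               n_boot = 1000L, seed = NULL) {
  stopifnot(nrow(w_matrix) == length(cells))
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  for (cell in unique(cells)) {
    sub <- w_matrix[cells == cell, , drop = FALSE] / 100
    for (g in colnames(w_matrix)) {
      fit <- fit_diet_mixture(sub[, g], min_nonzero = min_nonzero,
                              n_boot = n_boot)
      marker <- switch(fit$variant, reduced = "*", inapplicable = "X",
                       absent = "NA", "")
      label <- switch(fit$variant,
        absent = "NA",
        inapplicable = "X",
        sprintf("%.2f ± %.2f%s", 100 * fit$p,
                100 * ifelse(is.na(fit$se), 0, fit$se), marker))
      out[[length(out) + 1L]] <- data.frame(
        cell = cell, prey_group = g,
        estimate_pct = 100 * fit$p,
        se_pct = 100 * fit$se,
        variant = fit$variant, marker = marker, label = label,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
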