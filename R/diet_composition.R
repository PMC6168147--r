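#' Assign size class from fork length
#'
#' Species-specific fork-length breakpoints between approximate life stages:
#' gray triggerfish juveniles 111-183, sub-adults 184-283, adults 284-382 mm
#' FL; red snapper 145-222, 223-356, 357-570 mm FL.
#'
#' @param species character vector (`gray_triggerfish` or `red_snapper`).
#' @param fork_length numeric vector, mm FL.
#' @return character vector of size classes.
#' @export
assign_size_class <- function(species, fork_length) {
  stopifnot(length(species) == length(fork_length))
  if_stop(!all(species %in% .species_levels),
          paste("unknown species:",
                paste(setdiff(species, .species_levels), collapse = ", ")))
  juv_max <- c(gray_triggerfish = 183, red_snapper = 222)
  sub_max <- c(gray_triggerfish = 283, red_snapper = 356)
  out <- ifelse(fork_length <= juv_max[species], "juvenile",
                ifelse(fork_length <= sub_max[species], "sub_adult", "adult"))
  unname(out)
}

#' Filter guts for diet analysis
#'
#' A fish is excluded when its gut is empty or contains only
#' non-identifiable material (unidentifiable content, chyme, bait, parasites,
#' inorganic items); any single identifiable prey item retains the gut.
#'
#' @param records gut-content data frame with columns `fish_id`,
#'   `prey_group`, `content_flag`, `count`, `dry_weight`.
#' @param fish fish data frame with a `fish_id` column.
#' @return list with `included` (fish ids), `excluded` (data frame of
#'   `fish_id` and `reason`).
#' @export
filter_guts <- function(records, fish) {
  orphan <- setdiff(records$fish_id, fish$fish_id)
  if_stop(length(orphan) > 0,
          paste("gut records reference unknown fish:",
                paste(utils::head(orphan, 5), collapse = ", ")))
  reasons <- vapply(fish$fish_id, function(id) {
    rows <- records[records$fish_id == id, , drop = FALSE]
    if (nrow(rows) == 0) return("empty")
    ok <- rows$content_flag == "identifiable"
    if (any(ok)) return("")
    flags <- sort(unique(rows$content_flag))
    paste0(paste(flags, collapse = "+"), "-only")
  }, character(1))
  list(
    included = fish$fish_id[reasons == ""],
    excluded = data.frame(fish_id = fish$fish_id[reasons != ""],
                          reason = unname(reasons[reasons != ""]),
                          stringsAsFactors = FALSE)
  )
}

#' Restrict analysis to prey groups above a dry-weight share threshold
#'
#' Drops rare prey groups whose share of the total identifiable dry weight
#' falls below `threshold_pct` (default 1%, the conventional cut that reduced
#' 16 field categories to 7 quantitative groups).
#'
#' @param records identifiable gut-content records.
#' @param threshold_pct minimum percent share of total dry weight (>= rule).
#' @return list with `retained` (character vector) and `shares` (named
#'   percent shares of all groups).
#' @export
restrict_prey_groups <- function(records, threshold_pct = 1.0) {
  rec <- records[records$content_flag == "identifiable" &
                   !is.na(records$prey_group), , drop = FALSE]
  total <- sum(rec$dry_weight)
  if_stop(!is.finite(total) || total <= 0, "no identifiable content")
  shares <- 100 * tapply(rec$dry_weight, rec$prey_group, sum) / total
  shares <- shares[order(-shares)]
  list(retained = names(shares)[shares >= threshold_pct],
       shares = shares)
}

#' Diet composition metrics for one set of guts
#'
#' Computes, per prey group over the included guts:
#' %FO (percent of guts containing the group), %N (percent of all counted
#' prey individuals), and %W (percent of total dry weight). %N and %W each
#' sum to 100 over the included groups.
#'
#' @param records identifiable gut-content records (pre-filtered).
#' @param include_fish character vector of fish ids to use.
#' @param prey_groups prey groups to report (rows with other groups are
#'   dropped); defaults to all groups present.
#' @return data frame with columns `prey_group`, `pct_fo`, `pct_n`, `pct_w`
#'   and attribute `n_guts`.
#' @export
composition_summary <- function(records, include_fish,
                                prey_groups = NULL) {
  if_stop(length(include_fish) == 0, "no guts included")
  rec <- records[records$fish_id %in% include_fish &
                   records$content_flag == "identifiable" &
                   !is.na(records$prey_group), , drop = FALSE]
  if (is.null(prey_groups)) prey_groups <- sort(unique(rec$prey_group))
  rec <- rec[rec$prey_group %in% prey_groups, , drop = FALSE]
  if_stop(nrow(rec) == 0, "no identifiable content in included guts")
  n_guts <- length(include_fish)
  counts <- ifelse(is.na(rec$count) | rec$count < 1, 1L, rec$count)
  out <- data.frame(prey_group = prey_groups, stringsAsFactors = FALSE)
  out$pct_fo <- vapply(prey_groups, function(g) {
    100 * length(unique(rec$fish_id[rec$prey_group == g])) / n_guts
  }, numeric(1))
  tot_n <- sum(counts); tot_w <- sum(rec$dry_weight)
  out$pct_n <- vapply(prey_groups, function(g) {
    100 * sum(counts[rec$prey_group == g]) / tot_n
  }, numeric(1))
  out$pct_w <- vapply(prey_groups, function(g) {
    100 * sum(rec$dry_weight[rec$prey_group == g]) / tot_w
  }, numeric(1))
  attr(out, "n_guts") <- n_guts
  rownames(out) <- NULL
  out
}

#' Percent index of relative importance
#'
#' Pinkas-style index integrating occurrence, numeric and gravimetric
#' measures: IRI_g = (%N_g + %W_g) x %FO_g, normalized so %IRI sums to 100
#' over groups with positive IRI.
#'
#' @param summary a [composition_summary()] data frame.
#' @return the data frame with columns `iri` and `pct_iri` appended.
#' @export
percent_iri <- function(summary) {
  stopifnot(all(c("pct_fo", "pct_n", "pct_w") %in% names(summary)))
  iri <- (summary$pct_n + summary$pct_w) * summary$pct_fo
  if_stop(sum(iri) <= 0, "no identifiable prey")
  summary$iri <- iri
  summary$pct_iri <- 100 * iri / sum(iri)
  summary
}

#' Per-gut percent-weight matrix
#'
#' Builds the guts x prey-groups matrix of %W values (each row sums to 100)
#' used for Bray-Curtis / PERMANOVA / SIMPER analyses.
#'
#' @param records identifiable gut records.
#' @param include_fish fish ids to use as rows.
#' @param prey_groups column order; defaults to groups present.
#' @return numeric matrix with fish ids as rownames.
#' @export
percent_weight_matrix <- function(records, include_fish, prey_groups = NULL) {
  rec <- records[records$fish_id %in% include_fish &
                   records$content_flag == "identifiable" &
                   !is.na(records$prey_group), , drop = FALSE]
  if (is.null(prey_groups)) prey_groups <- sort(unique(rec$prey_group))
  rec <- rec[rec$prey_group %in% prey_groups, , drop = FALSE]
  m <- matrix(0, nrow = length(include_fish), ncol = length(prey_groups),
              dimnames = list(include_fish, prey_groups))
  if (nrow(rec)) {
    agg <- stats::aggregate(dry_weight ~ fish_id + prey_group, data = rec, sum)
    m[cbind(agg$fish_id, agg$prey_group)] <- agg$dry_weight
  }
  rs <- rowSums(m)
  if_stop(any(rs <= 0),
          paste("guts with zero identifiable weight (filter first):",
                paste(utils::head(include_fish[rs <= 0], 5), collapse = ", ")))
  100 * m / rs
}

#' Square-root transformed Bray-Curtis dissimilarity matrix
#'
#' Element-wise square root of the per-gut %W matrix followed by Bray-Curtis
#' dissimilarity, BC(i,j) = 1 - 2 sum_g min(x_ig, x_jg) / sum_g (x_ig + x_jg).
#' The square root damps the influence of dominant prey groups.
#'
#' @param w_matrix guts x groups matrix of %W values (rows sum to 100).
#' @param transform `"sqrt"` (default) or `"none"`.
#' @return a symmetric dissimilarity matrix in \[0, 1\] with zero diagonal.
#' @export
braycurtis_matrix <- function(w_matrix, transform = c("sqrt", "none")) {
  transform <- match.arg(transform)
  if_stop(nrow(w_matrix) < 2, "need at least 2 guts")
  if_stop(any(rowSums(w_matrix) <= 0), "a gut row is all zeros")
  x <- if (transform == "sqrt") sqrt(w_matrix) else w_matrix
  d <- as.matrix(vegan::vegdist(x, method = "bray"))
  dimnames(d) <- list(rownames(w_matrix), rownames(w_matrix))
  d
}
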