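# Schema-validated CSV round trip and the end-to-end report pipeline.

.schema <- list(
  fish = c("fish_id", "species", "region", "fork_length", "size_class"),
  guts = c("fish_id", "taxon", "family", "prey_group", "count",
           "dry_weight", "content_flag"),
  isotopes = c("fish_id", "d13c", "d15n", "d34s"),
  sources = c("sample_id", "source", "d13c", "d15n")
)

# configurable plausibility bounds; violations warn, never fail
.iso_bounds <- list(d13c = c(-35, -5), d15n = c(0, 25), d34s = c(10, 25))

#' Write a dataset bundle to CSV files
#'
#' Emits `fish.csv`, `guts.csv`, `isotopes.csv`, `sources.csv` (UTF-8,
#' comma-separated, `.` decimal) into a directory.
#'
#' @param bundle a `dataset_bundle` (see [generate_study()]).
#' @param dir output directory (created if missing).
#' @return the directory path, invisibly.
#' @export
write_dataset <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(.schema)) {
    utils::write.csv(bundle[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Load and validate a dataset bundle from CSV files
#'
#' Reads the four tables, checks the schemas, referential integrity (every
#' gut and isotope row references a known fish, at most one isotope triple
#' per fish, source rows are POM or BMA) and plausibility (isotope values
#' within configurable bounds, size class consistent with the fork-length
#' breakpoints). Plausibility problems warn; `strict = TRUE` upgrades them
#' to errors.
#'
#' @param dir directory containing `fish.csv`, `guts.csv`, `isotopes.csv`
#'   and (optionally) `sources.csv`.
#' @param strict upgrade plausibility warnings to errors.
#' @return a `dataset_bundle`.
#' @export
load_dataset <- function(dir, strict = FALSE) {
  warn_or_stop <- function(msg) {
    if (strict) if_stop(TRUE, msg) else warning(msg, call. = FALSE)
  }
  tables <- list()
  for (nm in names(.schema)) {
    path <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(path)) {
      if_stop(nm != "sources", paste("missing required file:", path))
      tables[nm] <- list(NULL)
      next
    }
    tb <- utils::read.csv(path, stringsAsFactors = FALSE)
    missing <- setdiff(.schema[[nm]], names(tb))
    if_stop(length(missing) > 0,
            paste0(nm, ".csv missing columns: ",
                   paste(missing, collapse = ", ")))
    tables[[nm]] <- tb
  }
  fish <- tables$fish; guts <- tables$guts; iso <- tables$isotopes
  orphan_g <- setdiff(guts$fish_id, fish$fish_id)
  if_stop(length(orphan_g) > 0,
          paste("gut rows reference unknown fish:",
                paste(utils::head(orphan_g, 5), collapse = ", ")))
  orphan_i <- setdiff(iso$fish_id, fish$fish_id)
  if_stop(length(orphan_i) > 0,
          paste("isotope rows reference unknown fish:",
                paste(utils::head(orphan_i, 5), collapse = ", ")))
  dup <- iso$fish_id[duplicated(iso$fish_id)]
  if_stop(length(dup) > 0,
          paste("duplicate isotope rows for fish:",
                paste(utils::head(dup, 5), collapse = ", ")))
  if (!is.null(tables$sources)) {
    bad <- setdiff(unique(tables$sources$source), c("POM", "BMA"))
    if_stop(length(bad) > 0,
            paste("unknown source type:", paste(bad, collapse = ", ")))
  }
  for (ax in names(.iso_bounds)) {
    b <- .iso_bounds[[ax]]
    out <- which(iso[[ax]] < b[1] | iso[[ax]] > b[2])
    if (length(out) > 0) {
      warn_or_stop(sprintf("%d %s value(s) outside plausible range [%g, %g] (rows %s)",
                           length(out), ax, b[1], b[2],
                           paste(utils::head(out, 5), collapse = ", ")))
    }
  }
  expected <- assign_size_class(fish$species, fish$fork_length)
  mism <- which(expected != fish$size_class)
  if (length(mism) > 0) {
    warn_or_stop(sprintf("size_class inconsistent with fork length for %d fish (rows %s)",
                         length(mism),
                         paste(utils::head(mism, 5), collapse = ", ")))
  }
  structure(c(tables,
              list(provenance = list(dir = normalizePath(dir),
                                     strict = strict))),
            class = "dataset_bundle")
}

#' Run the full reporting pipeline on a dataset bundle
#'
#' Orchestrates every analysis stage on a validated bundle and writes the
#' study-shaped tables as CSVs: sample sizes, per-cell %IRI, diet-mixture
#' contribution estimates (with the `*`/`X`/`NA` markers), pairwise
#' PERMANOVA + SIMPER, isotope means +/- SE, niche metrics with SEAc, and
#' the two-source mixing posterior summary per species x size class. A
#' manifest records the seed and configuration for exact re-runs. If the
#' bundle has no source table the mixing stage is skipped with a notice;
#' all other tables are still produced.
#'
#' @param bundle a `dataset_bundle`.
#' @param out_dir output directory for the CSV tables.
#' @param seed top-level seed; each stage uses [stage_seed()] sub-streams.
#' @param config list of stage knobs: `n_perm` (999), `n_boot_mixture`
#'   (200), `n_boot_niche` (1000), `mix_iterations` (10000), `mix_burn_in`
#'   (5000), `mix_chains` (3), `min_nonzero` (3), `threshold_pct` (1).
#' @return named list of the result tables (also written to `out_dir`),
#'   invisibly containing the manifest.
#' @export
run_report <- function(bundle, out_dir, seed = 1L, config = list()) {
  stopifnot(inherits(bundle, "dataset_bundle"))
  cfg <- utils::modifyList(list(
    n_perm = 999L, n_boot_mixture = 200L, n_boot_niche = 1000L,
    mix_iterations = 10000L, mix_burn_in = 5000L, mix_chains = 3L,
    min_nonzero = 3L, threshold_pct = 1.0), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fish <- bundle$fish; guts <- bundle$guts; iso <- bundle$isotopes
  results <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("report stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  # -- sample-size table ----------------------------------------------------
  results$sample_sizes <- stage("sample_sizes", {
    flt <- filter_guts(guts, fish)
    gut_fish <- fish[fish$fish_id %in% flt$included, ]
    tab_g <- stats::aggregate(fish_id ~ species + size_class + region,
                              data = gut_fish, FUN = length)
    names(tab_g)[4] <- "n_gut"
    iso_fish <- fish[fish$fish_id %in% iso$fish_id, ]
    tab_i <- stats::aggregate(fish_id ~ species + size_class + region,
                              data = iso_fish, FUN = length)
    names(tab_i)[4] <- "n_iso"
    out <- merge(tab_g, tab_i, all = TRUE)
    out$n_gut[is.na(out$n_gut)] <- 0L
    out$n_iso[is.na(out$n_iso)] <- 0L
    out
  })

  flt <- filter_guts(guts, fish)
  included <- flt$included
  results$exclusions <- flt$excluded

  # guts whose identifiable weight falls entirely in dropped (< threshold)
  # prey groups cannot enter %W-matrix analyses; itemize, never drop silently
  ids_with_retained <- function(ids, retained) {
    rec <- guts[guts$fish_id %in% ids & guts$content_flag == "identifiable" &
                  guts$prey_group %in% retained, , drop = FALSE]
    ok <- unique(rec$fish_id[rec$dry_weight > 0])
    dropped <- setdiff(ids, ok)
    if (length(dropped) > 0) {
      results$exclusions <<- rbind(
        results$exclusions,
        data.frame(fish_id = dropped, reason = "rare-prey-only",
                   stringsAsFactors = FALSE))
    }
    ids[ids %in% ok]
  }

  # -- prey-group restriction + per-cell %IRI -------------------------------
  fish_by_id <- fish[match(included, fish$fish_id), ]
  results$iri <- stage("iri", {
    out <- list()
    for (sp in unique(fish_by_id$species)) {
      ids_sp <- included[fish_by_id$species == sp]
      retained <- restrict_prey_groups(
        guts[guts$fish_id %in% ids_sp, ], cfg$threshold_pct)$retained
      for (by in c("size_class", "region")) {
        cells <- fish_by_id[[by]][fish_by_id$species == sp]
        for (cell in unique(cells)) {
          ids <- ids_sp[cells == cell]
          cs <- percent_iri(composition_summary(guts, ids, retained))
          cs$species <- sp; cs$grouping <- by; cs$cell <- cell
          cs$n_guts <- attr(cs, "n_guts")
          out[[length(out) + 1L]] <- cs
        }
      }
    }
    do.call(rbind, out)
  })

  # -- diet-mixture contribution table --------------------------------------
  results$mixture <- stage("mixture", {
    out <- list()
    for (sp in unique(fish_by_id$species)) {
      ids_sp <- included[fish_by_id$species == sp]
      retained <- restrict_prey_groups(
        guts[guts$fish_id %in% ids_sp, ], cfg$threshold_pct)$retained
      ids_sp <- ids_with_retained(ids_sp, retained)
      w <- percent_weight_matrix(guts, ids_sp, retained)
      for (by in c("size_class", "region")) {
        cells <- fish_by_id[[by]][match(ids_sp, fish_by_id$fish_id)]
        tb <- diet_mixture_table(w, cells, min_nonzero = cfg$min_nonzero,
                                 n_boot = cfg$n_boot_mixture,
                                 seed = stage_seed(seed, paste0("mixture_", sp, by)))
        tb$species <- sp; tb$grouping <- by
        out[[length(out) + 1L]] <- tb
      }
    }
    do.call(rbind, out)
  })

  # -- PERMANOVA pairwise + SIMPER ------------------------------------------
  results$permanova <- stage("permanova", {
    out <- list()
    for (sp in unique(fish_by_id$species)) {
      ids_sp <- included[fish_by_id$species == sp]
      retained <- restrict_prey_groups(
        guts[guts$fish_id %in% ids_sp, ], cfg$threshold_pct)$retained
      ids_sp <- ids_with_retained(ids_sp, retained)
      w <- percent_weight_matrix(guts, ids_sp, retained)
      D <- braycurtis_matrix(w)
      X <- sqrt(w)
      for (by in c("size_class", "region")) {
        cells <- fish_by_id[[by]][match(ids_sp, fish_by_id$fish_id)]
        keep <- cells %in% names(which(table(cells) >= 2))
        prs <- pairwise_permanova(D[keep, keep], cells[keep],
                                  n_perm = cfg$n_perm,
                                  seed = stage_seed(seed, paste0("perm_", sp, by)))
        for (nm in names(prs)) {
          pr <- prs[[nm]]
          sim <- simper_pairwise(X[keep, , drop = FALSE], cells[keep],
                                 strsplit(nm, " vs ")[[1]])
          out[[length(out) + 1L]] <- data.frame(
            species = sp, grouping = by, comparison = nm,
            t = pr$t_statistic, p_value = pr$p_perm,
            unique_perms = pr$unique_perms,
            dissimilarity_pct = sim$overall, stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, out)
  })

  # -- isotope means table ---------------------------------------------------
  iso_fish <- fish[match(iso$fish_id, fish$fish_id), ]
  results$isotope_means <- stage("isotope_means", {
    cells <- paste(iso_fish$species, iso_fish$region, iso_fish$size_class)
    isotope_group_summary(iso, cells)
  })

  # -- niche metrics table ---------------------------------------------------
  results$niche <- stage("niche", {
    out <- list()
    for (sp in unique(iso_fish$species)) {
      sel <- iso_fish$species == sp
      # size-class niches on raw values; regional niches on length-adjusted
      # values (size classes pooled within region)
      adj <- iso[sel, c("d13c", "d15n", "d34s")]
      for (ax in names(adj)) {
        adj[[ax]] <- length_adjust(adj[[ax]], iso_fish$fork_length[sel])$adjusted
      }
      for (by in c("size_class", "region")) {
        vals <- if (by == "size_class") iso[sel, c("d13c", "d15n", "d34s")]
                else adj
        cells <- iso_fish[[by]][sel]
        keep <- cells %in% names(which(table(cells) >= 3))
        ci <- bootstrap_metrics(vals[keep, ], cells[keep],
                                n_boot = cfg$n_boot_niche,
                                seed = stage_seed(seed, paste0("niche_", sp, by)))
        for (cell in unique(cells[keep])) {
          idx <- keep & cells == cell
          ell <- fit_standard_ellipse(vals[idx, c("d13c", "d15n")])
          lay <- layman_metrics(vals[idx, ])
          cic <- ci[ci$group == cell, ]
          row <- data.frame(
            species = sp, grouping = by, cell = cell, n = ell$n,
            sea = ell$sea, sea_c = ell$sea_c, cd = lay$cd,
            cr = lay$cr, nr = lay$nr, sr = lay$sr, stringsAsFactors = FALSE)
          for (mt in c("cd", "cr", "nr", "sr")) {
            row[[paste0(mt, "_lo")]] <- cic$lower[cic$metric == mt]
            row[[paste0(mt, "_hi")]] <- cic$upper[cic$metric == mt]
          }
          out[[length(out) + 1L]] <- row
        }
      }
    }
    do.call(rbind, out)
  })

  # -- two-source mixing models ---------------------------------------------
  if (is.null(bundle$sources)) {
    message("no source table: mixing stage skipped")
    results$mixing <- NULL
  } else {
    results$mixing <- stage("mixing", {
      src <- stats::aggregate(cbind(d13c, d15n) ~ source,
                              data = bundle$sources, FUN = mean)
      src_sd <- stats::aggregate(cbind(d13c, d15n) ~ source,
                                 data = bundle$sources, FUN = stats::sd)
      sources <- data.frame(source = src$source,
                            mean_d13c = src$d13c, mean_d15n = src$d15n,
                            sd_d13c = src_sd$d13c, sd_d15n = src_sd$d15n)
      prod_n <- pooled_producer_d15n(
        data.frame(mean_d15n = src$d15n,
                   n = as.integer(table(bundle$sources$source)[src$source])))
      out <- list()
      for (sp in unique(iso_fish$species)) {
        for (sc in unique(iso_fish$size_class)) {
          idx <- iso_fish$species == sp & iso_fish$size_class == sc
          if (sum(idx) < 3) next
          tl <- mean(trophic_level(iso$d15n[idx], prod_n))
          post <- fit_two_source_model(
            iso[idx, c("d13c", "d15n")], sources,
            steps = max(tl - 1, 0),
            iterations = cfg$mix_iterations, burn_in = cfg$mix_burn_in,
            chains = cfg$mix_chains,
            seed = stage_seed(seed, paste0("mix_", sp, sc)))
          sm <- summarize_posterior(post, force = TRUE)
          out[[length(out) + 1L]] <- data.frame(
            species = sp, size_class = sc, n = sum(idx),
            trophic_level = tl, steps = max(tl - 1, 0),
            p_pom_mean = sm$table$mean[1], p_pom_sd = sm$table$sd[1],
            p_bma_mean = sm$table$mean[2], p_bma_sd = sm$table$sd[2],
            max_rhat = max(post$rhat), converged = post$converged,
            stringsAsFactors = FALSE)
        }
      }
      do.call(rbind, out)
    })
  }

  results$exclusions <- unique(results$exclusions)

  # -- write tables + manifest ----------------------------------------------
  for (nm in names(results)) {
    if (is.null(results[[nm]])) next
    utils::write.csv(results[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  manifest <- c(sprintf("seed: %d", seed),
                sprintf("%s: %s", names(cfg), unlist(cfg)),
                sprintf("tables: %s", paste(names(results), collapse = ", ")))
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  results$manifest <- manifest
  invisible(results)
}
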