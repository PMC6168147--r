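# Internal helpers shared across modules.

#' Stop with a classed validation error
#' @noRd
if_stop <- function(cond, msg, class = "isoforage_validation_error") {
  if (cond) {
    stop(structure(
      class = c(class, "error", "condition"),
      list(message = msg, call = sys.call(-1))
    ))
  }
  invisible(NULL)
}

#' Derive a reproducible sub-stream seed from a top-level seed and a stage name
#'
#' All pipeline randomness flows from one top-level integer seed; each stage
#' draws from its own sub-stream so stages can be re-run independently yet
#' reproducibly. Kept strictly below 2^31 - 1.
#' @param seed integer top-level seed.
#' @param stage character stage label.
#' @return integer seed for the stage.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 7919 + h * 104729) %% .Machine$integer.max)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# canonical factor levels used throughout
.species_levels <- c("gray_triggerfish", "red_snapper")
.region_levels <- c("east", "central", "west")
.size_levels <- c("juvenile", "sub_adult", "adult")
.prey_levels <- c("barnacles", "bivalves", "cnidarians", "crabs",
                  "fish", "gastropods", "stomatopods")
.flag_levels <- c("identifiable", "unidentifiable", "chyme", "bait",
                  "parasite", "inorganic")
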