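#' Study design for the six-site, eight-round leaf sampling campaign
#'
#' Encodes the sampling arithmetic of the field design: six sites sampled in
#' eight seasonal rounds, with 80 leaves per site and round pooled into four
#' metabarcoding samples, plus 10 leaves per site and round washed into two
#' BC-particle suspensions imaged as five z-stacks of 35 slices each. Each
#' site carries a phylloplane BC-load category (`bcL`, `bcM`, `bcH`).
#'
#' @param sites Character vector of site identifiers.
#' @param rounds Number of sampling rounds (events).
#' @param leaves_per_site_round_meta Leaves collected per site and round for
#'   metabarcoding.
#' @param leaves_per_site_round_bc Leaves per site and round for BC imaging.
#' @param pools_per_site_round Pooled metabarcoding samples per site and round.
#' @param bc_samples_per_site_round BC leaf-wash suspensions per site & round.
#' @param stacks_per_sample Z-stacks imaged per BC suspension.
#' @param slices_per_stack Z-slices per stack.
#' @param category_map Named character vector mapping every site to one of
#'   `"bcL"`, `"bcM"`, `"bcH"`.
#' @return An object of class `study_design` (a validated list).
#' @examples
#' d <- study_design()
#' enumerate_design(d)
#' @export
study_design <- function(sites = c("HGa", "HGb", "HKa", "HKb", "DM", "DW"),
                         rounds = 8L,
                         leaves_per_site_round_meta = 80L,
                         leaves_per_site_round_bc = 10L,
                         pools_per_site_round = 4L,
                         bc_samples_per_site_round = 2L,
                         stacks_per_sample = 5L,
                         slices_per_stack = 35L,
                         category_map = c(HGa = "bcM", HGb = "bcM",
                                          HKa = "bcH", HKb = "bcH",
                                          DM = "bcL", DW = "bcL")) {
  if (length(sites) < 1L || anyDuplicated(sites))
    abort("`sites` must be non-empty and unique.", class = "phyllobc_invalid_design")
  counts <- c(rounds = rounds,
              leaves_per_site_round_meta = leaves_per_site_round_meta,
              leaves_per_site_round_bc = leaves_per_site_round_bc,
              pools_per_site_round = pools_per_site_round,
              bc_samples_per_site_round = bc_samples_per_site_round,
              stacks_per_sample = stacks_per_sample,
              slices_per_stack = slices_per_stack)
  bad <- names(counts)[!is.finite(counts) | counts < 1 | counts != floor(counts)]
  if (length(bad))
    abort(paste0("design counts must be positive integers; invalid: ",
                 paste(bad, collapse = ", ")),
          class = "phyllobc_invalid_design")
  if (!all(sites %in% names(category_map)))
    abort("`category_map` must cover every site.",
          class = "phyllobc_invalid_design")
  if (!all(category_map[sites] %in% c("bcL", "bcM", "bcH")))
    abort("categories must be bcL, bcM or bcH.",
          class = "phyllobc_invalid_design")
  structure(list(sites = as.character(sites),
                 rounds = as.integer(rounds),
                 leaves_per_site_round_meta = as.integer(leaves_per_site_round_meta),
                 leaves_per_site_round_bc = as.integer(leaves_per_site_round_bc),
                 pools_per_site_round = as.integer(pools_per_site_round),
                 bc_samples_per_site_round = as.integer(bc_samples_per_site_round),
                 stacks_per_sample = as.integer(stacks_per_sample),
                 slices_per_stack = as.integer(slices_per_stack),
                 category_map = category_map[sites]),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat("<study_design> ", length(x$sites), " sites x ", x$rounds, " rounds\n",
      sep = "")
  cat("  sites: ", paste0(x$sites, " (", x$category_map, ")",
                          collapse = ", "), "\n", sep = "")
  s <- enumerate_design(x)
  cat("  leaves: ", s$total_leaves, " (", s$leaves_meta, " metabarcoding + ",
      s$leaves_bc, " BC)\n", sep = "")
  cat("  samples: ", s$pooled_samples, " pooled metabarcoding, ",
      s$bc_samples, " BC suspensions, ", s$zstacks, " z-stacks\n", sep = "")
  invisible(x)
}

#' Totals implied by a study design
#'
#' Expands a `study_design` into the exact totals of the campaign: leaves
#' collected, pooled metabarcoding samples, BC suspensions, z-stacks, and
#' image slices per BC sample. All quantities are exact products of the
#' design counts.
#'
#' @param design A [study_design()].
#' @return A one-row tibble with columns `leaves_meta`, `leaves_bc`,
#'   `total_leaves`, `pooled_samples`, `bc_samples`, `zstacks`,
#'   `slices_per_sample`.
#' @examples
#' enumerate_design(study_design())
#' @export
enumerate_design <- function(design) {
  stopifnot(inherits(design, "study_design"))
  sr <- length(design$sites) * design$rounds
  leaves_meta <- sr * design$leaves_per_site_round_meta
  leaves_bc <- sr * design$leaves_per_site_round_bc
  pooled <- sr * design$pools_per_site_round
  bc_samples <- sr * design$bc_samples_per_site_round
  tibble(
    leaves_meta = leaves_meta,
    leaves_bc = leaves_bc,
    total_leaves = leaves_meta + leaves_bc,
    pooled_samples = pooled,
    bc_samples = bc_samples,
    zstacks = bc_samples * design$stacks_per_sample,
    slices_per_sample = design$stacks_per_sample * design$slices_per_stack
  )
}

#' Season label for a sampling round
#'
#' Rounds follow two annual cycles of four seasons, starting in autumn
#' (round 1 = autumn year 1, round 2 = winter, ..., round 5 = autumn year 2).
#'
#' @param round Integer vector of round indices (1-based).
#' @return Character vector of season labels.
#' @examples
#' round_season(1:8)
#' @export
round_season <- function(round) {
  if (any(round < 1 | round != floor(round)))
    abort("`round` must contain positive integers.")
  c("autumn", "winter", "spring", "summer")[((as.integer(round) - 1L) %% 4L) + 1L]
}
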