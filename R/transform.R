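#' Drop shallow samples from an ASV experiment
#'
#' Removes samples whose total read count is strictly less than `min_reads`
#' (the workflow's default of 500 reads), preserving sample order.
#'
#' @param x An [asv_experiment()].
#' @param min_reads Minimum total reads a sample must reach to be kept.
#' @return A filtered `asv_experiment`.
#' @examples
#' sim <- simulate_community(config = community_sim_config(n_taxa = 40), seed = 1)
#' filter_samples(sim$experiment, min_reads = 500)
#' @export
filter_samples <- function(x, min_reads = 500L) {
  stopifnot(inherits(x, "asv_experiment"))
  keep <- colSums(x$counts) >= min_reads
  if (!any(keep))
    abort("all samples fall below `min_reads`.", class = "phyllobc_empty_table")
  meta <- if (!is.null(x$metadata))
    x$metadata[x$metadata$sample_id %in% colnames(x$counts)[keep], ]
  asv_experiment(x$counts[, keep, drop = FALSE], x$taxonomy, meta)
}

#' Remove taxa whose lineage matches a label
#'
#' Drops taxa whose taxonomy contains `label` at any rank (case-insensitive
#' substring match); used to discard host chloroplast reads before
#' diversity analysis.
#'
#' @param x An [asv_experiment()] with taxonomy.
#' @param label Lineage label to purge (default `"Chloroplast"`).
#' @return A filtered `asv_experiment`.
#' @export
remove_taxa_by_lineage <- function(x, label = "Chloroplast") {
  stopifnot(inherits(x, "asv_experiment"))
  if (is.null(x$taxonomy))
    abort("taxonomy required for lineage-based removal.")
  ranks <- setdiff(names(x$taxonomy), "taxon")
  lin <- as.matrix(x$taxonomy[ranks])
  hit <- apply(lin, 1, function(r)
    any(grepl(label, r, ignore.case = TRUE), na.rm = TRUE))
  if (!any(hit)) return(x)
  keep <- x$taxonomy$taxon[!hit]
  asv_experiment(x$counts[keep, , drop = FALSE],
                 x$taxonomy[!hit, ], x$metadata)
}

#' Log-scale and normalise counts to even sampling depth
#'
#' Applies the workflow's beta-diversity transform: each count is scaled by
#' `S(x) = log10(x + 1)`, then every sample column is normalised to an even
#' depth of 1e6, i.e. `N(y) = y / sum(y) * 1e6`. Column sums of the result
#' are exactly 1e6 (to numerical precision).
#'
#' @param x An [asv_experiment()] or a bare counts matrix.
#' @return A numeric matrix (taxa x samples) of class `abundance_matrix`,
#'   with attribute `transform = "log10p1_per_million"`.
#' @examples
#' m <- matrix(c(9, 99), 2, 1, dimnames = list(c("a", "b"), "s1"))
#' transform_counts(m)
#' @export
transform_counts <- function(x) {
  counts <- if (inherits(x, "asv_experiment")) x$counts else x
  if (any(counts < 0)) abort("counts must be non-negative.")
  y <- log10(counts + 1)
  cs <- colSums(y)
  if (any(cs == 0))
    abort("all-zero sample column: per-million normalisation undefined.",
          class = "phyllobc_zero_sample")
  out <- sweep(y, 2, cs, "/") * 1e6
  attr(out, "transform") <- "log10p1_per_million"
  class(out) <- c("abundance_matrix", class(out))
  out
}

#' Per-million relative abundance (no log scaling)
#'
#' Straight closure of counts to a per-million scale, the input scale of the
#' indicator (LDA effect size) analysis.
#'
#' @inheritParams transform_counts
#' @return Matrix of class `abundance_matrix`, columns summing to 1e6.
#' @export
relative_abundance <- function(x) {
  counts <- if (inherits(x, "asv_experiment")) x$counts else x
  cs <- colSums(counts)
  if (any(cs == 0))
    abort("all-zero sample column: relative abundance undefined.",
          class = "phyllobc_zero_sample")
  out <- sweep(counts, 2, cs, "/") * 1e6
  attr(out, "transform") <- "per_million"
  class(out) <- c("abundance_matrix", class(out))
  out
}
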