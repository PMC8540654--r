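#' Bundle an ASV count matrix with taxonomy and sample metadata
#'
#' Light container tying together the three tables the community analyses
#' operate on: an integer count matrix (taxa x samples), a taxonomy tibble
#' (one row per taxon, ranked lineage columns), and a sample-metadata tibble
#' (one row per sample). Row/column ids are validated for uniqueness and
#' cross-table agreement.
#'
#' @param counts Non-negative numeric matrix, taxa in rows (rownames = taxon
#'   ids), samples in columns (colnames = sample ids).
#' @param taxonomy Optional tibble/data frame with a `taxon` column plus rank
#'   columns (e.g. kingdom...genus), covering every row of `counts`.
#' @param metadata Optional tibble/data frame with a `sample_id` column
#'   covering every column of `counts`.
#' @return An object of class `asv_experiment`.
#' @export
asv_experiment <- function(counts, taxonomy = NULL, metadata = NULL) {
  assert_counts_matrix(counts)
  if (!is.null(taxonomy)) {
    taxonomy <- as_tibble(taxonomy)
    if (!"taxon" %in% names(taxonomy))
      abort("`taxonomy` needs a `taxon` column.")
    if (!all(rownames(counts) %in% taxonomy$taxon))
      abort("`taxonomy` must cover every taxon in `counts`.")
    taxonomy <- taxonomy[match(rownames(counts), taxonomy$taxon), ]
  }
  if (!is.null(metadata)) {
    metadata <- as_tibble(metadata)
    if (!"sample_id" %in% names(metadata))
      abort("`metadata` needs a `sample_id` column.")
    if (!all(colnames(counts) %in% metadata$sample_id))
      abort("`metadata` must cover every sample in `counts`.")
    metadata <- metadata[match(colnames(counts), metadata$sample_id), ]
  }
  structure(list(counts = counts, taxonomy = taxonomy, metadata = metadata),
            class = "asv_experiment")
}

#' @export
print.asv_experiment <- function(x, ...) {
  cat("<asv_experiment> ", nrow(x$counts), " taxa x ", ncol(x$counts),
      " samples (", sum(x$counts), " reads)\n", sep = "")
  if (!is.null(x$taxonomy))
    cat("  taxonomy ranks: ",
        paste(setdiff(names(x$taxonomy), "taxon"), collapse = ", "), "\n",
        sep = "")
  if (!is.null(x$metadata))
    cat("  metadata: ", paste(names(x$metadata), collapse = ", "), "\n",
        sep = "")
  invisible(x)
}

#' @export
dim.asv_experiment <- function(x) dim(x$counts)

#' Per-sample grouping labels from experiment metadata
#' @param x An `asv_experiment`.
#' @param group Metadata column name (e.g. `"bc_category"`, `"season"`).
#' @return Character vector aligned with `colnames(x$counts)`.
#' @export
sample_groups <- function(x, group) {
  stopifnot(inherits(x, "asv_experiment"))
  if (is.null(x$metadata) || !group %in% names(x$metadata))
    abort(sprintf("metadata column `%s` not found.", group))
  as.character(x$metadata[[group]])
}
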