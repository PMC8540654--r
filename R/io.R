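#' Write an ASV experiment to TSV files
#'
#' Writes three UTF-8, Unix-newline TSVs: `asv_table.tsv` (first column
#' `taxon`, one integer column per sample), `taxonomy.tsv` (taxon + rank
#' columns) and `metadata.tsv` (one row per sample).
#'
#' @param x An [asv_experiment()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_asv_experiment <- function(x, dir) {
  stopifnot(inherits(x, "asv_experiment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(counts = file.path(dir, "asv_table.tsv"),
             taxonomy = file.path(dir, "taxonomy.tsv"),
             metadata = file.path(dir, "metadata.tsv"))
  counts_df <- as_tibble(x$counts, rownames = "taxon")
  readr::write_tsv(counts_df, paths["counts"])
  if (!is.null(x$taxonomy)) readr::write_tsv(x$taxonomy, paths["taxonomy"])
  if (!is.null(x$metadata)) readr::write_tsv(x$metadata, paths["metadata"])
  invisible(paths)
}

#' Read an ASV experiment from TSV files
#'
#' Counterpart of [write_asv_experiment()]. Validates the schema: a `taxon`
#' first column, non-negative integer counts, unique ids, and metadata
#' coverage; violations name the offending column or row.
#'
#' @param counts_path Path to the counts TSV.
#' @param taxonomy_path,metadata_path Optional companion TSV paths.
#' @return An [asv_experiment()].
#' @export
read_asv_experiment <- function(counts_path, taxonomy_path = NULL,
                                metadata_path = NULL) {
  df <- readr::read_tsv(counts_path, show_col_types = FALSE)
  if (names(df)[1] != "taxon")
    abort("counts file must have `taxon` as its first column.")
  counts <- as.matrix(df[-1])
  if (!is.numeric(counts))
    abort("count columns must be numeric.")
  neg <- which(counts < 0, arr.ind = TRUE)
  if (nrow(neg))
    abort(sprintf("negative count at taxon `%s`, sample `%s`.",
                  df$taxon[neg[1, 1]], colnames(counts)[neg[1, 2]]))
  rownames(counts) <- df$taxon
  taxonomy <- if (!is.null(taxonomy_path))
    readr::read_tsv(taxonomy_path, show_col_types = FALSE)
  metadata <- if (!is.null(metadata_path))
    readr::read_tsv(metadata_path, show_col_types = FALSE)
  asv_experiment(counts, taxonomy, metadata)
}

#' Write / read a square distance matrix as TSV
#'
#' Square layout with a `sample_id` first column and one column per sample;
#' reading validates symmetry and the zero diagonal.
#'
#' @param d Square symmetric matrix.
#' @param path File path.
#' @return `write_distance_matrix()` returns `path` invisibly;
#'   `read_distance_matrix()` returns the validated matrix.
#' @export
write_distance_matrix <- function(d, path) {
  d <- unclass(as.matrix(d))
  assert_square_distance(d)
  readr::write_tsv(as_tibble(d, rownames = "sample_id"), path)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[-1])
  rownames(m) <- df$sample_id
  if (!identical(rownames(m), colnames(m)))
    abort("distance matrix row/column ids disagree.")
  if (max(abs(m - t(m))) > 1e-8) {
    bad <- which(abs(m - t(m)) > 1e-8, arr.ind = TRUE)[1, ]
    abort(sprintf("asymmetric cell at (%s, %s).",
                  rownames(m)[bad[1]], colnames(m)[bad[2]]))
  }
  assert_square_distance(m)
  m
}

#' Write / read a z-stack channel pair as multi-page TIFF
#'
#' One 32-bit float TIFF per channel, one page per z-slice. Intensities are
#' rescaled to [0, 1] by the pair's global maximum on write (the detection
#' pipeline is invariant to this positive rescaling); the scale factor is
#' not stored.
#'
#' @param zstack A `zstack_pair`.
#' @param shg_path,af_path Output TIFF paths.
#' @return Invisibly, the two paths.
#' @export
write_zstack_pair <- function(zstack, shg_path, af_path) {
  mx <- max(max(zstack$shg), max(zstack$af), 1e-12)
  to_pages <- function(a) lapply(seq_len(dim(a)[3]), function(z) a[, , z] / mx)
  tiff::writeTIFF(to_pages(zstack$shg), shg_path, bits.per.sample = 32L)
  tiff::writeTIFF(to_pages(zstack$af), af_path, bits.per.sample = 32L)
  invisible(c(shg = shg_path, af = af_path))
}

#' @rdname write_zstack_pair
#' @param voxel_size Voxel edge lengths (um) to attach on read.
#' @export
read_zstack_pair <- function(shg_path, af_path,
                             voxel_size = c(425.1 / 64, 425.1 / 64, 35.1 / 35)) {
  read_stack <- function(p) {
    pages <- tiff::readTIFF(p, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    arr <- array(0, c(dim(pages[[1]])[1], dim(pages[[1]])[2], length(pages)))
    for (z in seq_along(pages)) arr[, , z] <- pages[[z]]
    arr
  }
  shg <- read_stack(shg_path)
  af <- read_stack(af_path)
  if (!identical(dim(shg), dim(af)))
    abort("channel stacks have different shapes.")
  structure(list(shg = shg, af = af, voxel_size = as.numeric(voxel_size),
                 truth = NULL),
            class = "zstack_pair")
}
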