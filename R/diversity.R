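#' Alpha diversity per sample
#'
#' Observed richness (taxa with count > 0) and the Shannon diversity index
#' `H = -sum(p_i * log(p_i))` over within-sample proportions. Natural
#' logarithm by default (the vegan convention), switchable via `base`.
#'
#' @param x An [asv_experiment()] or counts matrix (taxa x samples).
#' @param base Logarithm base for Shannon H.
#' @return Tibble: `sample_id`, `observed`, `shannon`, joined with sample
#'   metadata when available.
#' @examples
#' m <- matrix(c(1, 1, 2), 3, 1, dimnames = list(paste0("t", 1:3), "s1"))
#' alpha_diversity(m)
#' @export
alpha_diversity <- function(x, base = exp(1)) {
  counts <- if (inherits(x, "asv_experiment")) x$counts else x
  if (any(colSums(counts) == 0))
    abort("empty sample: alpha diversity undefined.",
          class = "phyllobc_zero_sample")
  shannon <- apply(counts, 2, function(v) {
    p <- v[v > 0] / sum(v)
    -sum(p * log(p, base = base))
  })
  out <- tibble(sample_id = colnames(counts),
                observed = unname(colSums(counts > 0)),
                shannon = as.numeric(shannon))
  if (inherits(x, "asv_experiment") && !is.null(x$metadata))
    out <- left_join(out, x$metadata, by = "sample_id")
  out
}

#' Rarefaction curves by subsampling without replacement
#'
#' Mean observed richness per sample at each requested depth, averaged over
#' `reps` random subsamples drawn without replacement (multivariate
#' hypergeometric). Depths exceeding a sample's total are skipped with a
#' warning.
#'
#' @param x An [asv_experiment()] or counts matrix.
#' @param depths Integer vector of rarefaction depths.
#' @param reps Subsamples per depth.
#' @param seed Integer seed.
#' @return Long tibble: `sample_id`, `depth`, `mean_observed`.
#' @examples
#' m <- matrix(c(5, 5, 10, 0, 3, 7), 3, 2,
#'             dimnames = list(paste0("t", 1:3), c("s1", "s2")))
#' rarefaction_curves(m, depths = c(1, 5, 10), reps = 10, seed = 1)
#' @export
rarefaction_curves <- function(x, depths, reps = 20L, seed = NULL) {
  counts <- if (inherits(x, "asv_experiment")) x$counts else x
  depths <- sort(unique(as.integer(depths)))
  if (any(depths < 1)) abort("`depths` must be >= 1.")
  with_seed(seed, {
    res <- purrr::map_dfr(colnames(counts), function(s) {
      v <- counts[, s]
      total <- sum(v)
      ok <- depths <= total
      if (any(!ok))
        warn(sprintf("sample %s: skipping depths beyond its total of %d reads.",
                     s, total))
      d_ok <- depths[ok]
      if (!length(d_ok)) return(tibble())
      pool <- rep.int(seq_along(v), v)
      mo <- vapply(d_ok, function(d) {
        mean(vapply(seq_len(reps), function(r)
          length(unique(sample(pool, d))), numeric(1)))
      }, numeric(1))
      tibble(sample_id = s, depth = d_ok, mean_observed = mo)
    })
    res
  })
}

#' Expected rarefied richness (hypergeometric closed form)
#'
#' Exact expectation of observed richness when drawing `depth` reads without
#' replacement: `sum_i (1 - choose(N - n_i, d) / choose(N, d))`. Used as the
#' analytic counterpart of [rarefaction_curves()].
#'
#' @param v Integer count vector for one sample.
#' @param depth Subsampling depth (<= sum(v)).
#' @return Expected number of taxa observed.
#' @export
expected_rarefied_richness <- function(v, depth) {
  N <- sum(v)
  if (depth > N) abort("`depth` exceeds the sample total.")
  v <- v[v > 0]
  sum(1 - exp(lchoose(N - v, depth) - lchoose(N, depth)))
}
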