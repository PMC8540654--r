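#' Bray-Curtis dissimilarity between samples
#'
#' `d(a, b) = sum(|a_i - b_i|) / sum(a_i + b_i)` over taxa, for every pair of
#' sample columns. Zero diagonal, symmetric, entries in [0, 1]. Computed on
#' whatever abundance scale the input carries; the workflow applies it to
#' the log/per-million transform of [transform_counts()].
#'
#' @param m Abundance matrix (taxa x samples), e.g. from
#'   [transform_counts()].
#' @return Square symmetric numeric matrix (samples x samples) of class
#'   `bc_distance`.
#' @examples
#' m <- cbind(s1 = c(1, 1), s2 = c(1, 0))
#' bray_curtis(m)["s1", "s2"] # 1/3
#' @export
bray_curtis <- function(m) {
  m <- unclass(m)
  if (!is.matrix(m) || ncol(m) < 2)
    abort("need an abundance matrix with >= 2 sample columns.")
  if (any(m < 0)) abort("abundances must be non-negative.")
  cs <- colSums(m)
  if (any(cs == 0))
    abort("all-zero sample: Bray-Curtis undefined for empty profiles.")
  num <- as.matrix(dist(t(m), method = "manhattan"))
  den <- outer(cs, cs, "+")
  d <- num / den
  diag(d) <- 0
  dimnames(d) <- list(colnames(m), colnames(m))
  class(d) <- c("bc_distance", class(d))
  d
}

#' Principal coordinate analysis (classical MDS, Gower centering)
#'
#' Eigendecomposes the double-centred matrix `-0.5 * J d^2 J` and returns
#' coordinates `v_j * sqrt(lambda_j)` for the `k` largest positive
#' eigenvalues. Negative eigenvalues (possible for semi-metric
#' dissimilarities such as Bray-Curtis) are reported as-is, without Cailliez
#' or Lingoes correction. If fewer than `k` positive eigenvalues exist, the
#' dimension is reduced with a warning.
#'
#' @param d Square symmetric dissimilarity matrix.
#' @param k Number of ordination axes requested.
#' @return Object of class `c("pcoa_ordination", "ordination")`: `points`
#'   (n x k matrix), `eigenvalues` (all n), `var_explained` (share of the
#'   positive-eigenvalue sum), `method`.
#' @examples
#' xy <- cbind(x = c(0, 3, 0), y = c(0, 0, 4))
#' d <- as.matrix(dist(xy))
#' ord <- pcoa(d, k = 2)
#' dist(ord$points) # recovers the input distances
#' @export
pcoa <- function(d, k = 2L) {
  d <- unclass(as.matrix(d))
  assert_square_distance(d)
  n <- nrow(d)
  if (k < 1) abort("`k` must be >= 1.")
  a <- -0.5 * d^2
  ctr <- diag(n) - matrix(1 / n, n, n)
  b <- ctr %*% a %*% ctr
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  pos <- which(e$values > max(e$values) * 1e-12 & e$values > 0)
  if (length(pos) < k) {
    warn(sprintf("only %d positive eigenvalues; reducing k from %d.",
                 length(pos), k))
    k <- length(pos)
  }
  if (k == 0L) abort("no positive eigenvalues: ordination degenerate.")
  idx <- pos[seq_len(k)]
  pts <- e$vectors[, idx, drop = FALSE] %*%
    diag(sqrt(e$values[idx]), k, k)
  dimnames(pts) <- list(rownames(d), paste0("Axis", seq_len(k)))
  structure(list(points = pts,
                 eigenvalues = e$values,
                 var_explained = e$values[idx] / sum(e$values[e$values > 0]),
                 method = "PCoA"),
            class = c("pcoa_ordination", "ordination"))
}

#' Nonmetric multidimensional scaling of a dissimilarity matrix
#'
#' Minimises Kruskal stress-1 by monotone regression (vegan's engine) from
#' multiple random starts, keeping the best solution. The reported `stress`
#' is the stress-1 fraction in [0, 1]; `converged` records whether any start
#' met the convergence criteria. Deterministic for a fixed `seed`.
#'
#' @param d Square symmetric dissimilarity matrix.
#' @param k Ordination dimension.
#' @param restarts Random starts.
#' @param seed Integer seed.
#' @param maxit Maximum iterations per start.
#' @return Object of class `c("nmds_ordination", "ordination")`: `points`,
#'   `stress`, `converged`, `method`.
#' @export
nmds <- function(d, k = 2L, restarts = 20L, seed = NULL, maxit = 300L) {
  d <- unclass(as.matrix(d))
  assert_square_distance(d)
  if (nrow(d) <= k) abort("need more samples than ordination dimensions.")
  fit <- with_seed(seed, suppressWarnings(suppressMessages(
    tryCatch(
      vegan::metaMDS(stats::as.dist(d), k = k, try = restarts,
                     trymax = restarts, maxit = maxit, trace = 0,
                     autotransform = FALSE, wascores = FALSE),
      # near-zero-stress configurations can abort the restart machinery;
      # a single monotone-regression fit from the metric-scaling start is
      # exact there
      error = function(e)
        vegan::monoMDS(stats::as.dist(d), k = k, maxit = maxit)
    )
  )))
  pts <- fit$points
  dimnames(pts) <- list(rownames(d), paste0("Axis", seq_len(ncol(pts))))
  structure(list(points = pts,
                 stress = fit$stress,
                 converged = isTRUE(fit$converged) ||
                   (is.numeric(fit$converged) && fit$converged > 0),
                 method = "NMDS"),
            class = c("nmds_ordination", "ordination"))
}

#' @export
print.ordination <- function(x, ...) {
  cat("<", x$method, " ordination> ", nrow(x$points), " samples, ",
      ncol(x$points), " axes", sep = "")
  if (!is.null(x$stress)) cat(", stress ", signif(x$stress, 4), sep = "")
  if (!is.null(x$eigenvalues))
    cat(", first-axes variance ",
        paste(sprintf("%.1f%%", 100 * x$var_explained), collapse = "/"),
        sep = "")
  cat("\n")
  invisible(x)
}

#' @rdname tidy_phyllobc
#' @export
tidy.ordination <- function(x, ...) {
  out <- as_tibble(x$points, rownames = "sample_id")
  out
}

#' @rdname glance_phyllobc
#' @export
glance.ordination <- function(x, ...) {
  tibble(method = x$method,
         n = nrow(x$points),
         k = ncol(x$points),
         stress = x$stress %||% NA_real_,
         converged = x$converged %||% NA,
         negative_eigenvalues = if (is.null(x$eigenvalues)) NA_integer_
                                else sum(x$eigenvalues < 0))
}
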