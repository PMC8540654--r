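# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run code with a locally set RNG seed
#'
#' Restores (or removes) the global `.Random.seed` afterwards so that seeded
#' package functions do not perturb the caller's RNG stream.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

# derive a stream-specific sub-seed from a master seed; double-precision
# arithmetic keeps the product exact and the result inside 32-bit range
sub_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 7919 + as.numeric(stream) * 104729) %%
               2147483629)
}

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort(sprintf("`%s` must be a single finite number.", name))
  if (positive && x <= 0)
    abort(sprintf("`%s` must be > 0.", name))
  invisible(x)
}

assert_counts_matrix <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    abort("`counts` must be a numeric matrix (taxa x samples).")
  if (any(!is.finite(counts)) || any(counts < 0))
    abort("`counts` must be finite and non-negative.")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    abort("`counts` must have taxon rownames and sample colnames.")
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts)))
    abort("duplicate taxon or sample ids in `counts`.")
  invisible(counts)
}

assert_square_distance <- function(d, tol = 1e-8) {
  if (!is.matrix(d) || nrow(d) != ncol(d))
    abort("distance matrix must be square.")
  if (max(abs(d - t(d))) > tol)
    abort("distance matrix must be symmetric.")
  if (max(abs(diag(d))) > tol)
    abort("distance matrix must have a zero diagonal.")
  invisible(d)
}
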