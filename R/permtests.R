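# shared validation for the two permutation tests
check_perm_groups <- function(d, groups) {
  d <- unclass(as.matrix(d))
  assert_square_distance(d)
  groups <- as.character(groups)
  if (length(groups) != nrow(d))
    abort("`groups` must have one label per sample.")
  tab <- table(groups)
  if (length(tab) < 2)
    abort("need at least two groups.")
  if (any(tab < 2))
    abort("every group needs at least two members.")
  list(d = d, groups = groups)
}

# all distinct permutations of a label vector (guarded enumeration)
enumerate_label_perms <- function(groups, limit = 50000L) {
  n <- length(groups)
  if (factorial(n) > limit)
    abort("exhaustive enumeration only supported for small n.")
  perm_idx <- function(v) {
    if (length(v) == 1L) return(matrix(v, 1, 1))
    do.call(rbind, lapply(seq_along(v), function(i)
      cbind(v[i], perm_idx(v[-i]))))
  }
  idx <- perm_idx(seq_len(n))
  unique(matrix(groups[idx], nrow(idx), n))
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based test of group separation on a dissimilarity matrix:
#' `R = (mean_between_rank - mean_within_rank) / (M/2)` with
#' `M = n(n-1)/2` pairwise dissimilarities ranked jointly (mid-ranks for
#' ties). Significance by permuting group labels; the permutation p-value
#' includes the observed statistic, `p = (1 + #{R* >= R}) / (1 + n_perm)`,
#' so it can never be zero. `exact = TRUE` enumerates all distinct label
#' permutations instead (small n only) and reports the exact tail
#' proportion.
#'
#' @param d Square symmetric dissimilarity matrix (e.g. [bray_curtis()]).
#' @param groups Group label per sample (>= 2 groups of >= 2).
#' @param n_perm Number of random label permutations.
#' @param seed Integer seed for the permutations.
#' @param exact Enumerate all label permutations (overrides `n_perm`).
#' @return Object of class `perm_test` with `statistic` (R), `effect_size`
#'   (R), `p_value`, `permutations`, `method`, `seed`.
#' @examples
#' sim <- simulate_community(config = community_sim_config(n_taxa = 60), seed = 2)
#' d <- bray_curtis(transform_counts(sim$experiment))
#' anosim(d, sample_groups(sim$experiment, "bc_category"),
#'        n_perm = 99, seed = 1)
#' @export
anosim <- function(d, groups, n_perm = 999L, seed = NULL, exact = FALSE) {
  x <- check_perm_groups(d, groups)
  n <- nrow(x$d)
  lower <- lower.tri(x$d)
  r <- rank(x$d[lower])
  M <- n * (n - 1) / 2
  pair_i <- row(x$d)[lower]
  pair_j <- col(x$d)[lower]
  stat_fun <- function(g) {
    w <- g[pair_i] == g[pair_j]
    (mean(r[!w]) - mean(r[w])) / (M / 2)
  }
  obs <- stat_fun(x$groups)
  if (exact) {
    perms <- enumerate_label_perms(x$groups)
    stats <- apply(perms, 1, stat_fun)
    p <- mean(stats >= obs - 1e-12)
    n_used <- nrow(perms)
  } else {
    stats <- with_seed(seed, vapply(seq_len(n_perm), function(i)
      stat_fun(sample(x$groups)), numeric(1)))
    p <- (1 + sum(stats >= obs - 1e-12)) / (1 + n_perm)
    n_used <- n_perm
  }
  structure(list(method = "ANOSIM", statistic_name = "R",
                 statistic = obs, effect_size = obs,
                 p_value = p, permutations = n_used,
                 null_statistics = stats, seed = seed,
                 groups = sort(unique(x$groups))),
            class = "perm_test")
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' One-factor partitioning of the total sum of squared dissimilarities:
#' `SS_total = sum_{i<j} d_ij^2 / n`, `SS_within = sum_g sum_{i<j in g}
#' d_ij^2 / n_g`, `SS_between = SS_total - SS_within`; pseudo-F =
#' `(SS_between/(a-1)) / (SS_within/(n-a))` and `R^2 =
#' SS_between/SS_total`. Significance by label permutation with the same
#' +1-corrected p as [anosim()].
#'
#' @inheritParams anosim
#' @return Object of class `perm_test` with `statistic` (pseudo-F),
#'   `effect_size` (R^2), `p_value`, `permutations`, `ss` breakdown.
#' @export
permanova <- function(d, groups, n_perm = 999L, seed = NULL, exact = FALSE) {
  x <- check_perm_groups(d, groups)
  n <- nrow(x$d)
  d2 <- x$d^2
  lower <- lower.tri(d2)
  pair_i <- row(d2)[lower]
  pair_j <- col(d2)[lower]
  d2v <- d2[lower]
  ss_total <- sum(d2v) / n
  a <- length(unique(x$groups))
  f_from_ssw <- function(ssw) (ss_total - ssw) / (a - 1) / (ssw / (n - a))
  ssw_fun <- function(g) {
    w <- g[pair_i] == g[pair_j]
    gs <- tapply(d2v[w], g[pair_i][w], sum)
    ng <- table(g)
    sum(gs / as.numeric(ng[names(gs)]))
  }
  ssw_obs <- ssw_fun(x$groups)
  obs <- f_from_ssw(ssw_obs)
  r2 <- (ss_total - ssw_obs) / ss_total
  if (exact) {
    perms <- enumerate_label_perms(x$groups)
    stats <- apply(perms, 1, function(g) f_from_ssw(ssw_fun(g)))
    p <- mean(stats >= obs - 1e-12)
    n_used <- nrow(perms)
  } else {
    stats <- with_seed(seed, vapply(seq_len(n_perm), function(i)
      f_from_ssw(ssw_fun(sample(x$groups))), numeric(1)))
    p <- (1 + sum(stats >= obs - 1e-12)) / (1 + n_perm)
    n_used <- n_perm
  }
  structure(list(method = "PERMANOVA", statistic_name = "pseudo-F",
                 statistic = obs, effect_size = r2,
                 p_value = p, permutations = n_used,
                 ss = c(total = ss_total, within = ssw_obs,
                        between = ss_total - ssw_obs),
                 null_statistics = stats, seed = seed,
                 groups = sort(unique(x$groups))),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat("<", x$method, "> ", x$statistic_name, " = ",
      signif(x$statistic, 4), sep = "")
  if (x$method == "PERMANOVA")
    cat(", R2 = ", signif(x$effect_size, 4), sep = "")
  cat(", p = ", signif(x$p_value, 4), " (", x$permutations,
      " permutations)\n", sep = "")
  invisible(x)
}

#' Tidy methods for phyllobc result objects
#'
#' @param x A fitted phyllobc object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidy_phyllobc
NULL

#' Glance methods for phyllobc result objects
#'
#' @param x A fitted phyllobc object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @name glance_phyllobc
NULL

#' @rdname tidy_phyllobc
#' @export
tidy.perm_test <- function(x, ...) {
  tibble(method = x$method,
         statistic = x$statistic,
         statistic_name = x$statistic_name,
         effect_size = x$effect_size,
         p_value = x$p_value,
         permutations = x$permutations)
}

#' @rdname glance_phyllobc
#' @export
glance.perm_test <- function(x, ...) tidy(x)
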