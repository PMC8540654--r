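#' Aggregate ASV counts to a taxonomic rank
#'
#' Sums counts over ASVs sharing a rank label (genus, family, order, class,
#' ...) and converts to per-million relative abundance. ASVs lacking a label
#' at the rank are pooled under `"unclassified_<parent label>"`, where the
#' parent is the nearest higher rank with a label.
#'
#' @param x An [asv_experiment()] with taxonomy.
#' @param rank Rank column name present in the taxonomy.
#' @return Matrix (rank taxa x samples, per-million scale) of class
#'   `abundance_matrix`, with attribute `rank`.
#' @examples
#' sim <- simulate_community(config = community_sim_config(n_taxa = 40), seed = 3)
#' genus <- aggregate_to_rank(sim$experiment, "genus")
#' colSums(genus)[1:3] # each 1e6
#' @export
aggregate_to_rank <- function(x, rank) {
  stopifnot(inherits(x, "asv_experiment"))
  if (is.null(x$taxonomy)) abort("taxonomy required.")
  ranks <- setdiff(names(x$taxonomy), "taxon")
  if (!rank %in% ranks)
    abort(sprintf("rank `%s` absent from taxonomy (have: %s).",
                  rank, paste(ranks, collapse = ", ")))
  lab <- as.character(x$taxonomy[[rank]])
  if (any(is.na(lab) | lab == "")) {
    higher <- rev(ranks[seq_len(match(rank, ranks) - 1)])
    for (i in which(is.na(lab) | lab == "")) {
      parent <- "root"
      for (h in higher) {
        v <- as.character(x$taxonomy[[h]][i])
        if (!is.na(v) && v != "") { parent <- v; break }
      }
      lab[i] <- paste0("unclassified_", parent)
    }
  }
  agg <- rowsum(x$counts, lab)
  rel <- relative_abundance(agg)
  attr(rel, "rank") <- rank
  rel
}

#' Kruskal-Wallis screen for differentially abundant taxa
#'
#' Per-taxon Kruskal-Wallis rank-sum test (tie-corrected H, chi-square
#' p-value via [stats::kruskal.test()]) across the group labels; taxa with
#' `p < alpha` are flagged as candidates. Taxa constant across all samples
#' have no defined p and are excluded with a note column.
#'
#' @param m Abundance matrix (taxa x samples), e.g. from
#'   [aggregate_to_rank()].
#' @param groups Group label per sample (>= 2 groups of >= 2 samples).
#' @param alpha Candidate threshold on the raw p-value.
#' @return Tibble: `taxon`, `h_statistic`, `p_value`, `candidate`, `note`.
#' @export
kruskal_wallis_screen <- function(m, groups, alpha = 0.05) {
  m <- unclass(m)
  groups <- as.character(groups)
  if (length(groups) != ncol(m))
    abort("`groups` must have one label per sample column.")
  tab <- table(groups)
  if (length(tab) < 2 || any(tab < 2))
    abort("need >= 2 groups with >= 2 samples each.")
  g <- factor(groups)
  res <- purrr::map_dfr(rownames(m), function(tx) {
    v <- m[tx, ]
    if (length(unique(v)) == 1L)
      return(tibble(taxon = tx, h_statistic = NA_real_, p_value = NA_real_,
                    candidate = FALSE, note = "constant across samples"))
    kt <- suppressWarnings(kruskal.test(v, g))
    tibble(taxon = tx, h_statistic = unname(kt$statistic),
           p_value = kt$p.value,
           candidate = is.finite(kt$p.value) && kt$p.value < alpha,
           note = NA_character_)
  })
  attr(res, "alpha") <- alpha
  res
}

# ridge-regularised first linear discriminant on a feature matrix
# (samples x features); returns the unit-norm discriminant vector
first_discriminant <- function(X, g, ridge = 1e-6) {
  g <- factor(g)
  p <- ncol(X)
  mu <- colMeans(X)
  Sw <- matrix(0, p, p)
  Sb <- matrix(0, p, p)
  for (lv in levels(g)) {
    Xi <- X[g == lv, , drop = FALSE]
    mi <- colMeans(Xi)
    ci <- sweep(Xi, 2, mi)
    Sw <- Sw + crossprod(ci)
    Sb <- Sb + nrow(Xi) * tcrossprod(mi - mu)
  }
  eps <- ridge * (mean(diag(Sw)) + 1)
  Sw <- Sw + diag(eps, p)
  e <- eigen(solve(Sw, Sb))
  u <- Re(e$vectors[, 1])
  u / sqrt(sum(u^2))
}

#' LDA effect size of candidate taxa (LEfSe-style)
#'
#' Estimates, for each candidate taxon, a discriminant-based effect size on
#' the per-million abundance scale. Per bootstrap subsample (fraction 2/3 of
#' each class, 30 rounds by default), a ridge-regularised linear
#' discriminant is fitted jointly on all classes over the candidate
#' features; for every class pair the per-feature effect is the average of
#' the absolute between-class difference of feature means and the absolute
#' displacement along the discriminant axis attributed to the feature
#' (`|u_j| * |proj mean difference|`), and the feature's bootstrap effect is
#' the maximum over class pairs. The final raw effect is the mean over
#' bootstraps and the reported score is its log10. The enriched category is
#' the class with the highest overall mean abundance (one-vs-rest). Rows are
#' retained when `score >= score_threshold`; the unfiltered scores remain
#' available in attribute `"all_scores"`.
#'
#' @param m Abundance matrix (taxa x samples, per-million scale).
#' @param groups Class label per sample (each class n >= 3).
#' @param candidates Character vector of candidate taxa (typically the
#'   `candidate` rows of [kruskal_wallis_screen()]).
#' @param n_boot Bootstrap rounds.
#' @param boot_fraction Per-class subsample fraction.
#' @param seed Integer seed.
#' @param score_threshold Minimum log10 score to report (the conventional 2
#'   corresponds to a 100-per-million effect).
#' @param ridge Ridge regularisation for the within-class scatter.
#' @return Tibble of class `indicator_table`: `taxon`, `enriched_group`,
#'   `raw_effect`, `lda_score`; attribute `all_scores` holds every candidate.
#' @export
lda_effect_size <- function(m, groups, candidates, n_boot = 30L,
                            boot_fraction = 2 / 3, seed = NULL,
                            score_threshold = 2, ridge = 1e-6) {
  m <- unclass(m)
  groups <- as.character(groups)
  empty <- tibble(taxon = character(0), enriched_group = character(0),
                  raw_effect = numeric(0), lda_score = numeric(0))
  class(empty) <- c("indicator_table", class(empty))
  if (length(candidates) == 0L) {
    attr(empty, "all_scores") <- empty
    return(empty)
  }
  if (!all(candidates %in% rownames(m)))
    abort("unknown candidate taxa.")
  tab <- table(groups)
  if (any(tab < 3)) abort("every class needs n >= 3 for the bootstrap.")
  X_all <- t(m[candidates, , drop = FALSE]) # samples x features
  g_all <- factor(groups)
  p <- length(candidates)

  effects <- with_seed(seed, {
    boot_eff <- matrix(NA_real_, n_boot, p)
    for (b in seq_len(n_boot)) {
      idx <- unlist(lapply(levels(g_all), function(lv) {
        i <- which(g_all == lv)
        sample(i, max(3L, ceiling(boot_fraction * length(i))))
      }))
      X <- X_all[idx, , drop = FALSE]
      g <- droplevels(g_all[idx])
      u <- if (p == 1L) 1 else first_discriminant(X, g, ridge)
      proj <- drop(X %*% u)
      cls <- levels(g)
      cm <- vapply(cls, function(lv)
        colMeans(X[g == lv, , drop = FALSE]), numeric(p))
      cm <- matrix(cm, p, length(cls), dimnames = list(candidates, cls))
      pm <- vapply(cls, function(lv) mean(proj[g == lv]), numeric(1))
      best <- rep(0, p)
      for (i in seq_along(cls)[-length(cls)]) for (j in (i + 1):length(cls)) {
        gm <- abs(cm[, i] - cm[, j])
        coef_term <- abs(u) * abs(pm[i] - pm[j])
        best <- pmax(best, 0.5 * (gm + coef_term))
      }
      boot_eff[b, ] <- best
    }
    colMeans(boot_eff)
  })

  overall_means <- vapply(levels(g_all), function(lv)
    rowMeans(m[candidates, groups == lv, drop = FALSE]), numeric(p))
  overall_means <- matrix(overall_means, p, length(levels(g_all)),
                          dimnames = list(candidates, levels(g_all)))
  enriched <- colnames(overall_means)[max.col(overall_means, ties.method = "first")]

  all_scores <- tibble(taxon = candidates,
                       enriched_group = enriched,
                       raw_effect = effects,
                       lda_score = log10(pmax(effects, .Machine$double.xmin)))
  out <- all_scores[all_scores$lda_score >= score_threshold, ]
  out <- out[order(-out$lda_score), ]
  class(out) <- c("indicator_table", class(out))
  attr(out, "all_scores") <- all_scores
  out
}

#' Indicator taxa across taxonomic ranks
#'
#' End-to-end indicator analysis: aggregate to each requested rank, screen
#' with Kruskal-Wallis (`p < alpha`), score survivors by LDA effect size,
#' and keep taxa with score >= `score_threshold`. Every reported row
#' satisfies both thresholds exactly as filtered.
#'
#' @param x An [asv_experiment()] with taxonomy and metadata.
#' @param group Metadata column to contrast (default `"bc_category"`).
#' @param ranks Taxonomy ranks to scan.
#' @param alpha Kruskal-Wallis screen threshold.
#' @param score_threshold Minimum LDA log10 score.
#' @param seed Integer seed for the LDA bootstrap.
#' @inheritParams lda_effect_size
#' @return Tibble: `taxon`, `rank`, `rank_letter`, `enriched_group`,
#'   `kw_p_value`, `lda_score`, sorted by score within rank.
#' @examples
#' sim <- simulate_community(config = community_sim_config(n_taxa = 60), seed = 4)
#' indicator_taxa(sim$experiment, ranks = "genus", seed = 1)
#' @export
indicator_taxa <- function(x, group = "bc_category",
                           ranks = c("genus", "family", "order", "class"),
                           alpha = 0.05, score_threshold = 2,
                           n_boot = 30L, boot_fraction = 2 / 3,
                           seed = NULL) {
  stopifnot(inherits(x, "asv_experiment"))
  groups <- sample_groups(x, group)
  letters_map <- c(genus = "g", family = "f", order = "o", class = "c",
                   phylum = "p", kingdom = "k")
  purrr::map_dfr(seq_along(ranks), function(ri) {
    rk <- ranks[ri]
    m <- aggregate_to_rank(x, rk)
    screen <- kruskal_wallis_screen(m, groups, alpha)
    cand <- screen$taxon[screen$candidate]
    eff <- lda_effect_size(m, groups, cand,
                           n_boot = n_boot, boot_fraction = boot_fraction,
                           seed = sub_seed(seed, ri), score_threshold = score_threshold)
    if (nrow(eff) == 0L) return(tibble())
    out <- left_join(as_tibble(eff),
                     screen[, c("taxon", "p_value")], by = "taxon")
    rl <- unname(letters_map[rk])
    if (is.na(rl)) rl <- substr(rk, 1, 1)
    tibble(taxon = out$taxon,
           rank = rk,
           rank_letter = rl,
           enriched_group = out$enriched_group,
           kw_p_value = out$p_value,
           lda_score = out$lda_score)
  })
}
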