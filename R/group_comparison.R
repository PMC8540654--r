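#' One-way analysis of variance
#'
#' Classical one-way F test over group means, via [stats::aov()].
#'
#' @param data Data frame with the response and grouping columns.
#' @param value Name of the numeric response column.
#' @param group Name of the grouping column.
#' @return One-row tibble: `f_statistic`, `df_between`, `df_within`,
#'   `p_value`, `n`, `n_groups`.
#' @examples
#' df <- data.frame(v = rnorm(30), g = rep(letters[1:3], each = 10))
#' one_way_anova(df, "v", "g")
#' @export
one_way_anova <- function(data, value = "value", group = "group") {
  v <- data[[value]]
  g <- factor(data[[group]])
  if (is.null(v) || is.null(g)) abort("value/group columns not found.")
  tab <- table(g)
  if (length(tab) < 2 || any(tab < 2))
    abort("need >= 2 groups with n >= 2 each.")
  if (all(tapply(v, g, function(z) var(z) == 0)))
    abort("zero residual variance: F undefined.")
  fit <- anova(aov(v ~ g))
  tibble(f_statistic = fit$`F value`[1],
         df_between = fit$Df[1],
         df_within = fit$Df[2],
         p_value = fit$`Pr(>F)`[1],
         n = length(v),
         n_groups = length(tab))
}

#' Pairwise t tests with multiplicity correction
#'
#' Welch two-sided t tests (pooled-variance optional) for every unordered
#' pair of groups, corrected across the m pairs by Bonferroni
#' (`p_adj = min(1, m p)`) or Benjamini-Hochberg step-up.
#'
#' @inheritParams one_way_anova
#' @param correction `"bonferroni"` or `"bh"`.
#' @param var_equal Use the pooled-variance t test instead of Welch.
#' @return Tibble of class `pairwise_comparison`: `group_a`, `group_b`,
#'   `t_statistic`, `df`, `p_value`, `p_adjusted`, `correction`.
#' @examples
#' df <- data.frame(v = c(rnorm(10), rnorm(10, 3)), g = rep(c("a", "b"), each = 10))
#' pairwise_t_tests(df, "v", "g", correction = "bh")
#' @export
pairwise_t_tests <- function(data, value = "value", group = "group",
                             correction = c("bonferroni", "bh"),
                             var_equal = FALSE) {
  correction <- match.arg(correction)
  v <- data[[value]]
  g <- as.character(data[[group]])
  tab <- table(g)
  if (length(tab) < 2) abort("need at least two groups.")
  if (any(tab < 2)) abort("every group needs n >= 2.")
  lv <- names(tab)
  pairs <- utils::combn(lv, 2)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    tt <- t.test(v[g == a], v[g == b], var.equal = var_equal)
    tibble(group_a = a, group_b = b,
           t_statistic = unname(tt$statistic),
           df = unname(tt$parameter),
           p_value = tt$p.value)
  })
  res$p_adjusted <- p.adjust(res$p_value,
                             method = if (correction == "bh") "BH" else "bonferroni")
  res$correction <- correction
  class(res) <- c("pairwise_comparison", class(res))
  res
}

#' @rdname tidy_phyllobc
#' @export
tidy.pairwise_comparison <- function(x, ...) as_tibble(unclass(x))

#' Per-site significance letters in the field-table convention
#'
#' Encodes, for each site, the set of sites it differs from at adjusted
#' `p < alpha`, as superscript letters assigned `u, v, w, ...` in the fixed
#' site order (first site = u, second = v, ...).
#'
#' @param results A [pairwise_t_tests()] result over sites.
#' @param site_order Character vector fixing the site -> letter assignment.
#' @param alpha Significance level on the adjusted p.
#' @return Tibble: `site`, `letter`, `differs_from` (letter string),
#'   `n_significant`.
#' @export
significance_letters <- function(results,
                                 site_order = c("HGa", "HGb", "HKa", "HKb",
                                                "DM", "DW"),
                                 alpha = 0.05) {
  stopifnot(all(c("group_a", "group_b", "p_adjusted") %in% names(results)))
  used <- union(results$group_a, results$group_b)
  if (!all(used %in% site_order))
    abort("`site_order` must cover every site in `results`.")
  letter_of <- setNames(letters[20 + seq_along(site_order)], site_order) # u, v, w, ...
  sig <- results[results$p_adjusted < alpha, , drop = FALSE]
  purrr::map_dfr(site_order, function(s) {
    others <- c(sig$group_b[sig$group_a == s], sig$group_a[sig$group_b == s])
    others <- intersect(site_order, others) # fixed order
    tibble(site = s,
           letter = unname(letter_of[s]),
           differs_from = paste(letter_of[others], collapse = ""),
           n_significant = length(others))
  })
}
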