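test_that("rank aggregation sums counts and closes to per-million", {
  e <- make_tiny_experiment()
  gen <- aggregate_to_rank(e, "genus")
  # G3 pools ASV_3 and ASV_5; unclassified ASV_4 pools under its nearest
  # labelled parent rank (order = Chloroplast)
  expect_setequal(rownames(gen), c("G1", "G2", "G3",
                                   "unclassified_Chloroplast"))
  expect_equal(unname(colSums(gen)), rep(1e6, 4), tolerance = 1e-9)

  # two genera 3:1 in a sample -> 750000 / 250000
  counts <- matrix(c(3, 1), 2, 1, dimnames = list(c("a", "b"), "s"))
  tax <- tibble::tibble(taxon = c("a", "b"), genus = c("gA", "gB"))
  m <- aggregate_to_rank(asv_experiment(counts, tax), "genus")
  expect_equal(unname(m[c("gA", "gB"), 1]), c(750000, 250000))

  # all ASVs in one genus collapse to the column sums
  tax1 <- tibble::tibble(taxon = c("a", "b"), genus = "g")
  m1 <- aggregate_to_rank(asv_experiment(counts, tax1), "genus")
  expect_equal(unname(m1[1, 1]), 1e6)

  expect_error(aggregate_to_rank(asv_experiment(counts, tax), "species"))
})

test_that("aggregation commutes with summing counts", {
  sim <- simulate_community(config = community_sim_config(n_taxa = 40,
                                                          n_chloroplast_taxa = 0),
                            seed = 13)
  e <- sim$experiment
  agg_counts <- rowsum(e$counts, e$taxonomy$family)
  direct <- aggregate_to_rank(e, "family")
  via_totals <- relative_abundance(agg_counts)
  expect_equal(unclass(direct)[rownames(via_totals), ],
               unclass(via_totals), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("Kruskal-Wallis screen is calibrated and powered", {
  # null selection rate ~ alpha
  set.seed(14)
  g <- rep(c("a", "b", "c"), each = 8)
  hits <- vapply(1:300, function(i) {
    m <- matrix(rnorm(24), 1, 24, dimnames = list("t", paste0("s", 1:24)))
    kruskal_wallis_screen(m, g)$candidate
  }, logical(1))
  expect_lt(abs(mean(hits) - 0.05), 0.03)

  # 10-fold shift detected nearly always at n = 20/group
  g2 <- rep(c("a", "b"), each = 20)
  power_hits <- vapply(1:40, function(i) {
    v <- c(rlnorm(20, log(100), 0.5), rlnorm(20, log(1000), 0.5))
    m <- matrix(v, 1, 40, dimnames = list("t", paste0("s", 1:40)))
    kruskal_wallis_screen(m, g2)$candidate
  }, logical(1))
  expect_gte(mean(power_hits), 0.95)

  # two groups reduce to the tie-corrected Wilcoxon rank-sum test
  set.seed(15)
  v <- sample(1:8, 16, replace = TRUE) # ties on purpose
  m <- matrix(v, 1, 16, dimnames = list("t", paste0("s", 1:16)))
  g3 <- rep(c("a", "b"), each = 8)
  kw <- kruskal_wallis_screen(m, g3)
  wt <- suppressWarnings(wilcox.test(v[1:8], v[9:16], correct = FALSE))
  expect_equal(kw$p_value, wt$p.value, tolerance = 1e-10)

  # constant taxa are excluded with a note
  mc <- matrix(5, 1, 16, dimnames = list("const", paste0("s", 1:16)))
  sc <- kruskal_wallis_screen(mc, g3)
  expect_false(sc$candidate)
  expect_match(sc$note, "constant")
})

test_that("LDA effect size recovers planted indicators and filters exactly", {
  empty <- lda_effect_size(matrix(1, 1, 6, dimnames = list("t", paste0("s", 1:6))),
                           rep(c("a", "b"), each = 3), character(0))
  expect_equal(nrow(empty), 0)

  sim <- simulate_community(config = community_sim_config(n_taxa = 80),
                            seed = 16)
  e <- remove_taxa_by_lineage(sim$experiment)
  groups <- sample_groups(e, "bc_category")
  m <- aggregate_to_rank(e, "genus")
  screen <- kruskal_wallis_screen(m, groups)
  eff <- lda_effect_size(m, groups, screen$taxon[screen$candidate], seed = 4)

  # threshold semantics: every reported row passes both filters
  expect_true(all(eff$lda_score >= 2))
  sel <- screen[match(eff$taxon, screen$taxon), ]
  expect_true(all(sel$p_value < 0.05))

  # planted bc indicators dominate: recovery >= 80%, and the top score is
  # a planted genus
  truth_bc <- sim$truth[sim$truth$effect == "bc", ]
  planted_genera <- unique(e$taxonomy$genus[match(truth_bc$taxon,
                                                  e$taxonomy$taxon)])
  recovered <- mean(planted_genera %in% eff$taxon)
  expect_gte(recovered, 0.8)
  expect_true(eff$taxon[which.max(eff$lda_score)] %in% planted_genera)

  # enrichment assignment matches the planted category for recovered taxa
  hit <- eff[eff$taxon %in% planted_genera, ]
  tax_of_genus <- function(gn) {
    asvs <- e$taxonomy$taxon[e$taxonomy$genus %in% gn]
    truth_bc$enriched_level[truth_bc$taxon %in% asvs][1]
  }
  planted_cat <- vapply(hit$taxon, tax_of_genus, character(1))
  expect_gte(mean(hit$enriched_group == planted_cat, na.rm = TRUE), 0.8)
})

test_that("effect scores grow monotonically with the planted fold change", {
  folds <- c(2, 5, 10, 30)
  scores <- vapply(folds, function(f) {
    cfg <- community_sim_config(n_taxa = 60, bc_effect_taxa_fraction = 1 / 60,
                                bc_effect_multiplier = f,
                                season_effect_taxa_fraction = 0,
                                n_chloroplast_taxa = 0)
    sim <- simulate_community(study_design(), cfg, seed = 17)
    e <- sim$experiment
    groups <- sample_groups(e, "bc_category")
    m <- relative_abundance(e)
    tx <- sim$truth$taxon[1]
    eff <- lda_effect_size(m, groups, tx, seed = 2, score_threshold = -Inf)
    eff$lda_score[eff$taxon == tx]
  }, numeric(1))
  expect_true(all(diff(scores) > 0))
})

test_that("indicator_taxa reports ranked, letter-tagged indicators", {
  sim <- simulate_community(config = community_sim_config(n_taxa = 60),
                            seed = 18)
  e <- remove_taxa_by_lineage(sim$experiment)
  ind <- indicator_taxa(e, ranks = c("genus", "family"), seed = 6)
  expect_true(all(ind$rank_letter %in% c("g", "f")))
  expect_true(all(ind$lda_score >= 2))
  expect_true(all(ind$kw_p_value < 0.05))
  expect_true(all(ind$enriched_group %in% c("bcL", "bcM", "bcH")))
})
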