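small_design <- function() {
  study_design(sites = c("A", "B", "C"), rounds = 4,
               pools_per_site_round = 2,
               category_map = c(A = "bcL", B = "bcM", C = "bcH"))
}

test_that("community simulation is reproducible and respects the design", {
  cfg <- community_sim_config(n_taxa = 50)
  s1 <- simulate_community(small_design(), cfg, seed = 9)
  s2 <- simulate_community(small_design(), cfg, seed = 9)
  expect_identical(s1$experiment$counts, s2$experiment$counts)
  expect_identical(s1$truth, s2$truth)

  e <- s1$experiment
  expect_equal(ncol(e$counts), 3 * 4 * 2)
  expect_equal(nrow(e$counts), 50 + cfg$n_chloroplast_taxa)
  expect_setequal(unique(e$metadata$bc_category), c("bcL", "bcM", "bcH"))
  expect_equal(e$metadata$season, round_season(e$metadata$round))
  # taxonomy covers every taxon
  expect_setequal(e$taxonomy$taxon, rownames(e$counts))
})

test_that("fixed library range pins every sample total", {
  cfg <- community_sim_config(n_taxa = 30, library_size_range = c(500, 500),
                              n_chloroplast_taxa = 0)
  s <- simulate_community(small_design(), cfg, seed = 2)
  expect_true(all(colSums(s$experiment$counts) == 500))
})

test_that("planted effect ground truth matches the requested fractions", {
  cfg <- community_sim_config(n_taxa = 100, bc_effect_taxa_fraction = 0.2,
                              season_effect_taxa_fraction = 0.1)
  s <- simulate_community(small_design(), cfg, seed = 4)
  expect_equal(sum(s$truth$effect == "bc"), 20)
  expect_equal(sum(s$truth$effect == "season"), 10)
  expect_true(all(s$truth$enriched_level[s$truth$effect == "bc"] %in%
                    c("bcL", "bcM", "bcH")))
  # null config records no planted effects
  s0 <- simulate_community(small_design(),
                           community_sim_config(n_taxa = 30,
                                                bc_effect_multiplier = 1,
                                                season_effect_multiplier = 1),
                           seed = 1)
  expect_equal(nrow(s0$truth), 0)
})

test_that("over-requesting effect taxa and invalid configs error", {
  expect_error(community_sim_config(n_taxa = 10,
                                    bc_effect_taxa_fraction = 0.8,
                                    season_effect_taxa_fraction = 0.5))
  expect_error(community_sim_config(bc_effect_taxa_fraction = 1.2))
  expect_error(community_sim_config(bc_effect_multiplier = 0))
  expect_error(community_sim_config(library_size_range = c(0, 10)))
  expect_error(community_sim_config(dispersion = -1))
})

test_that("with unit multipliers, BC category carries no signal", {
  # mean ANOSIM R over null replicates is near zero
  des <- small_design()
  cfg <- community_sim_config(n_taxa = 40, bc_effect_multiplier = 1,
                              season_effect_multiplier = 1,
                              n_chloroplast_taxa = 0)
  rs <- vapply(1:20, function(i) {
    s <- simulate_community(des, cfg, seed = 100 + i)
    d <- bray_curtis(transform_counts(s$experiment))
    anosim(d, sample_groups(s$experiment, "bc_category"), n_perm = 0)$statistic
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("pollution series reproduces the designed seasonal structure", {
  # zero amplitude, zero noise: constant at the site mean
  sm <- tibble::tibble(site = c("X", "Y"), bc = c(1, 3))
  ps <- simulate_pollution_series(sm, seasonal_amplitudes = c(bc = 0),
                                  n_days = 10, noise_sd = c(bc = 0), seed = 1)
  expect_true(all(ps$value[ps$site == "X"] == 1))
  expect_true(all(ps$value[ps$site == "Y"] == 3))

  # series length matches the monitored two-year window
  ps2 <- simulate_pollution_series(n_days = 761, seed = 2)
  expect_equal(sort(unique(ps2$day)), 1:761)
  expect_equal(sum(ps2$site == "HGa" & ps2$pollutant == "bc"), 761)
  expect_true(all(ps2$value >= 0))

  # simulated site-mean rank order follows the reference means for BC
  bc_means <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(ps2, pollutant == "bc"), site),
    m = mean(value))
  ref <- reference_pollution_means()
  expect_equal(bc_means$site[order(-bc_means$m)][1], "HGa")
  expect_true(all(bc_means$site[order(bc_means$m)][1:2] %in% c("DM", "DW")))

  # NO2 and O3 seasonal components anti-phased: negative correlation of
  # their noise-free seasonal parts
  ps3 <- simulate_pollution_series(n_days = 365, noise_sd = 0, seed = 3)
  no2 <- ps3$value[ps3$site == "HGa" & ps3$pollutant == "no2"]
  o3 <- ps3$value[ps3$site == "HGa" & ps3$pollutant == "o3"]
  expect_lt(cor(no2, o3), -0.9)

  expect_error(simulate_pollution_series(tibble::tibble(site = "X", bc = -1)))
})
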