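#' Configuration of the Dirichlet-multinomial community simulator
#'
#' Parameters controlling the synthetic phylloplane community. Baseline
#' relative abundances follow a log-normal rank-abundance profile; a fraction
#' of taxa are "effect taxa" whose expected relative abundance is multiplied
#' in one BC-load category (or season); counts are drawn
#' Dirichlet-multinomial so samples are overdispersed relative to a pure
#' multinomial, as amplicon data are.
#'
#' Defaults encode the simulated study conditions: 300 taxa, log-normal
#' baseline (sdlog 1.5, a realistically skewed rank-abundance curve), 10% of
#' taxa responding to BC-load category with an 8-fold enrichment, 10%
#' responding to season with a 3-fold enrichment (BC effect deliberately
#' larger than the seasonal one), Dirichlet concentration 200, and library
#' sizes uniform in 5000-20000 reads.
#'
#' @param n_taxa Number of taxa (ASVs).
#' @param baseline_logmean,baseline_logsd Meanlog/sdlog of baseline
#'   abundances.
#' @param bc_effect_taxa_fraction Fraction of taxa enriched in one BC
#'   category.
#' @param bc_effect_multiplier Enrichment multiplier in the assigned
#'   category (>0; 1 disables the effect).
#' @param season_effect_taxa_fraction Fraction of taxa enriched in one
#'   season.
#' @param season_effect_multiplier Seasonal enrichment multiplier.
#' @param dispersion Dirichlet concentration scale (larger = less
#'   overdispersion).
#' @param library_size_range Length-2 integer range of reads per sample
#'   (uniform); min >= 1.
#' @param n_chloroplast_taxa Host-plastid taxa added with a `Chloroplast`
#'   lineage entry, to exercise lineage-based removal.
#' @return A validated list of class `community_sim_config`.
#' @export
community_sim_config <- function(n_taxa = 300L,
                                 baseline_logmean = 0,
                                 baseline_logsd = 1.5,
                                 bc_effect_taxa_fraction = 0.10,
                                 bc_effect_multiplier = 8,
                                 season_effect_taxa_fraction = 0.10,
                                 season_effect_multiplier = 3,
                                 dispersion = 200,
                                 library_size_range = c(5000L, 20000L),
                                 n_chloroplast_taxa = 2L) {
  if (n_taxa < 1) abort("`n_taxa` must be >= 1.")
  for (f in c(bc_effect_taxa_fraction, season_effect_taxa_fraction))
    if (f < 0 || f > 1) abort("effect-taxa fractions must lie in [0, 1].")
  if (bc_effect_multiplier <= 0 || season_effect_multiplier <= 0)
    abort("effect multipliers must be > 0.")
  if (dispersion <= 0) abort("`dispersion` must be > 0.")
  if (length(library_size_range) != 2L || library_size_range[1] < 1 ||
      library_size_range[2] < library_size_range[1])
    abort("`library_size_range` must be (min, max) with min >= 1.")
  n_bc <- round(bc_effect_taxa_fraction * n_taxa)
  n_season <- round(season_effect_taxa_fraction * n_taxa)
  if (n_bc + n_season > n_taxa)
    abort("`n_taxa` is smaller than the number of effect taxa requested.")
  structure(list(n_taxa = as.integer(n_taxa),
                 baseline_logmean = baseline_logmean,
                 baseline_logsd = baseline_logsd,
                 bc_effect_taxa_fraction = bc_effect_taxa_fraction,
                 bc_effect_multiplier = bc_effect_multiplier,
                 season_effect_taxa_fraction = season_effect_taxa_fraction,
                 season_effect_multiplier = season_effect_multiplier,
                 dispersion = dispersion,
                 library_size_range = as.integer(library_size_range),
                 n_chloroplast_taxa = as.integer(n_chloroplast_taxa)),
            class = "community_sim_config")
}

#' Simulate a phylloplane ASV experiment under the study design
#'
#' Draws one pooled metabarcoding sample per site x round x pool cell of the
#' design. Expected relative abundances start from a common log-normal
#' baseline; BC-effect taxa are multiplied by `bc_effect_multiplier` in their
#' assigned BC-load category and season-effect taxa by
#' `season_effect_multiplier` in their assigned season; per-sample
#' compositions are Dirichlet (concentration = `dispersion` x expected
#' relative abundance) and counts multinomial at a uniform random library
#' size. Metadata records site, round, season, BC category, leaf mass
#' (log-normal around 2 g) and the suspension volume (8 mL default, an
#' explicit assumption of the workflow).
#'
#' @param design A [study_design()].
#' @param config A [community_sim_config()].
#' @param seed Integer seed; identical seeds give identical experiments.
#' @return A list with `experiment` (an [asv_experiment()]) and `truth`, a
#'   tibble of planted effect taxa (`taxon`, `effect` = "bc"/"season",
#'   `enriched_level`, `multiplier`).
#' @examples
#' sim <- simulate_community(study_design(), community_sim_config(n_taxa = 50),
#'                           seed = 1)
#' sim$experiment
#' @export
simulate_community <- function(design = study_design(),
                               config = community_sim_config(),
                               seed = NULL) {
  stopifnot(inherits(design, "study_design"),
            inherits(config, "community_sim_config"))
  with_seed(seed, {
    n_taxa <- config$n_taxa + config$n_chloroplast_taxa
    taxa <- sprintf("ASV_%04d", seq_len(n_taxa))
    chloro <- if (config$n_chloroplast_taxa > 0)
      tail(taxa, config$n_chloroplast_taxa) else character(0)
    micro <- setdiff(taxa, chloro)

    base <- rlnorm(n_taxa, config$baseline_logmean, config$baseline_logsd)
    names(base) <- taxa

    n_bc <- round(config$bc_effect_taxa_fraction * config$n_taxa)
    n_season <- round(config$season_effect_taxa_fraction * config$n_taxa)
    eff_taxa <- sample(micro, n_bc + n_season)
    bc_taxa <- eff_taxa[seq_len(n_bc)]
    season_taxa <- setdiff(eff_taxa, bc_taxa)
    cats <- c("bcL", "bcM", "bcH")
    seasons <- c("autumn", "winter", "spring", "summer")
    bc_assign <- setNames(rep_len(cats, n_bc), bc_taxa)
    season_assign <- setNames(rep_len(seasons, n_season), season_taxa)

    meta <- expand.grid(pool = seq_len(design$pools_per_site_round),
                        round = seq_len(design$rounds),
                        site = design$sites,
                        stringsAsFactors = FALSE)
    meta <- tibble(
      sample_id = sprintf("%s_R%d_P%d", meta$site, meta$round, meta$pool),
      site = meta$site,
      round = meta$round,
      season = round_season(meta$round),
      bc_category = as.character(design$category_map[meta$site]),
      leaf_mass_g = round(rlnorm(nrow(meta), log(2), 0.15), 3),
      suspension_volume_ml = 8
    )

    libsz <- config$library_size_range
    sizes <- if (libsz[1] == libsz[2]) rep(libsz[1], nrow(meta))
             else sample(libsz[1]:libsz[2], nrow(meta), replace = TRUE)

    counts <- matrix(0L, n_taxa, nrow(meta),
                     dimnames = list(taxa, meta$sample_id))
    for (s in seq_len(nrow(meta))) {
      mu <- base
      bt <- bc_taxa[bc_assign == meta$bc_category[s]]
      mu[bt] <- mu[bt] * config$bc_effect_multiplier
      st <- season_taxa[season_assign == meta$season[s]]
      mu[st] <- mu[st] * config$season_effect_multiplier
      alpha <- config$dispersion * mu / sum(mu)
      p <- rgamma(n_taxa, shape = alpha, rate = 1)
      if (sum(p) <= 0) p <- mu # pathological dispersion underflow guard
      counts[, s] <- as.integer(rmultinom(1, sizes[s], p / sum(p)))
    }

    taxonomy <- synthetic_taxonomy(taxa, chloro)
    truth <- bind_rows(
      tibble(taxon = bc_taxa, effect = "bc",
             enriched_level = as.character(bc_assign),
             multiplier = config$bc_effect_multiplier),
      tibble(taxon = season_taxa, effect = "season",
             enriched_level = as.character(season_assign),
             multiplier = config$season_effect_multiplier)
    )
    if (config$bc_effect_multiplier == 1)
      truth <- truth[truth$effect != "bc", ]
    if (config$season_effect_multiplier == 1)
      truth <- truth[truth$effect != "season", ]

    list(experiment = asv_experiment(counts, taxonomy, meta), truth = truth)
  })
}

# deterministic hierarchical lineage: genera nested in families, orders,
# classes, phyla; chloroplast taxa carry the plastid lineage
synthetic_taxonomy <- function(taxa, chloro = character(0)) {
  n <- length(taxa)
  idx <- seq_len(n)
  tax <- tibble(
    taxon = taxa,
    kingdom = "Bacteria",
    phylum = sprintf("Phylum_%02d", ((idx - 1) %/% 60) + 1),
    class = sprintf("Class_%02d", ((idx - 1) %/% 30) + 1),
    order = sprintf("Order_%02d", ((idx - 1) %/% 15) + 1),
    family = sprintf("Family_%03d", ((idx - 1) %/% 5) + 1),
    genus = sprintf("Genus_%03d", ((idx - 1) %/% 2) + 1)
  )
  if (length(chloro)) {
    i <- tax$taxon %in% chloro
    tax$phylum[i] <- "Cyanobacteria"
    tax$class[i] <- "Chloroplast"
    tax$order[i] <- "Chloroplast"
    tax$family[i] <- NA_character_
    tax$genus[i] <- NA_character_
  }
  tax
}
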