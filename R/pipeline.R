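#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end run: the study design, community
#' and z-stack simulation parameters, detector settings, and statistics
#' settings. Round-trips losslessly through YAML via [write_pipeline_config()]
#' / [read_pipeline_config()].
#'
#' @param seed Master seed; all stage seeds are derived from it.
#' @param design A [study_design()].
#' @param community A [community_sim_config()].
#' @param n_stack_samples BC suspensions to image in the simulated run (a
#'   desk-scale subset of the design's suspensions).
#' @param stack_shape Simulated stack dimensions `c(x, y, z)` in voxels.
#' @param snr Simulated blob peak-to-background ratio.
#' @param threshold_fraction Detector relative-threshold fraction.
#' @param connectivity Particle connectivity (6, 18 or 26).
#' @param n_perm Permutations for ANOSIM/PERMANOVA.
#' @param alpha Significance level for screens and comparisons.
#' @param lda_threshold Minimum LDA log10 score for indicators.
#' @param correction Multiplicity correction for pairwise tests.
#' @param out_dir Output directory.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            design = study_design(),
                            community = community_sim_config(),
                            n_stack_samples = 6L,
                            stack_shape = c(64L, 64L, 35L),
                            snr = 5,
                            threshold_fraction = 0.001,
                            connectivity = 26L,
                            n_perm = 999L,
                            alpha = 0.05,
                            lda_threshold = 2,
                            correction = c("bh", "bonferroni"),
                            out_dir = tempfile("phyllobc_run_")) {
  correction <- match.arg(correction)
  structure(list(seed = as.integer(seed), design = design,
                 community = community,
                 n_stack_samples = as.integer(n_stack_samples),
                 stack_shape = as.integer(stack_shape), snr = snr,
                 threshold_fraction = threshold_fraction,
                 connectivity = as.integer(connectivity),
                 n_perm = as.integer(n_perm), alpha = alpha,
                 lda_threshold = lda_threshold, correction = correction,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return The path (write) or a reconstructed `pipeline_config` (read).
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  x$design <- unclass(x$design)
  x$design$category_map <- as.list(x$design$category_map)
  x$community <- unclass(x$community)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  cm <- unlist(x$design$category_map)
  design <- study_design(sites = x$design$sites, rounds = x$design$rounds,
                         leaves_per_site_round_meta = x$design$leaves_per_site_round_meta,
                         leaves_per_site_round_bc = x$design$leaves_per_site_round_bc,
                         pools_per_site_round = x$design$pools_per_site_round,
                         bc_samples_per_site_round = x$design$bc_samples_per_site_round,
                         stacks_per_sample = x$design$stacks_per_sample,
                         slices_per_stack = x$design$slices_per_stack,
                         category_map = cm)
  community <- do.call(community_sim_config, x$community)
  pipeline_config(seed = x$seed, design = design, community = community,
                  n_stack_samples = x$n_stack_samples,
                  stack_shape = x$stack_shape, snr = x$snr,
                  threshold_fraction = x$threshold_fraction,
                  connectivity = x$connectivity, n_perm = x$n_perm,
                  alpha = x$alpha, lda_threshold = x$lda_threshold,
                  correction = x$correction, out_dir = x$out_dir)
}

#' Run the full simulate-detect-analyse pipeline
#'
#' Executes the stages in order under a single master seed: (1) simulate the
#' community experiment and write its TSVs; (2) simulate z-stacks for a
#' subset of BC suspensions, detect particles by coincidence, and compute
#' per-sample loads and category fold changes; (3) filter samples, discard
#' chloroplast taxa, transform counts, compute Bray-Curtis distances, PCoA
#' and NMDS, and run ANOSIM/PERMANOVA for BC category and season; (4) alpha
#' diversity plus pairwise site comparisons; (5) genus-rank indicator taxa.
#' All outputs are written under `config$out_dir` and summarised in a JSON
#' manifest with md5 checksums, so identical configs and seeds give
#' identical manifests.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the manifest list (also written as `manifest.json`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  if (!dir.exists(out)) {
    dir.create(out, recursive = TRUE)
    message("created output directory ", out)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      abort(sprintf("pipeline stage `%s` failed: %s", name,
                    conditionMessage(e)),
            class = "phyllobc_stage_error"))
  }

  # 1. community simulation
  sim <- stage("simulate_community",
               simulate_community(config$design, config$community,
                                  seed = sub_seed(config$seed, 1L)))
  write_asv_experiment(sim$experiment, out)
  readr::write_tsv(sim$truth, file.path(out, "effect_truth.tsv"))

  # 2. BC imaging on a subset of suspensions
  bc <- stage("bc_imaging", {
    loads <- purrr::map_dfr(seq_len(config$n_stack_samples), function(s) {
      counts <- vapply(seq_len(config$design$stacks_per_sample), function(k) {
        zs <- simulate_zstack_pair(
          n_particles = 5L + (s %% 3L) * 5L, n_confounders = 3L,
          shape = config$stack_shape, snr = config$snr,
          seed = sub_seed(config$seed, 100L + s * 10L + k))
        detect_bc_particles(zs, config$threshold_fraction,
                            config$connectivity)$n_particles
      }, numeric(1))
      vol <- prod(config$stack_shape *
                    c(425.1 / config$stack_shape[1],
                      425.1 / config$stack_shape[2],
                      35.1 / config$stack_shape[3]))
      bc_load(counts, vol, 8,
              leaf_mass_g = 2,
              sample_id = sprintf("BC_%02d", s))
    })
    loads
  })
  readr::write_tsv(bc, file.path(out, "bc_loads.tsv"))
  ref <- reference_bc_loads()
  folds <- category_fold_change(setNames(ref$mean_load, ref$site),
                                setNames(ref$bc_category, ref$site))
  readr::write_tsv(folds, file.path(out, "bc_fold_changes.tsv"))

  # 3. community statistics
  stats_out <- stage("community_stats", {
    exp2 <- remove_taxa_by_lineage(filter_samples(sim$experiment), "Chloroplast")
    ab <- transform_counts(exp2)
    d <- bray_curtis(ab)
    write_distance_matrix(d, file.path(out, "bray_curtis.tsv"))
    ordp <- pcoa(d, k = 2)
    ordn <- nmds(d, k = 2, restarts = 5,
                 seed = sub_seed(config$seed, 3L))
    readr::write_tsv(tidy(ordp), file.path(out, "pcoa_coordinates.tsv"))
    readr::write_tsv(tidy(ordn), file.path(out, "nmds_coordinates.tsv"))
    tests <- bind_rows(
      mutate(tidy(anosim(d, sample_groups(exp2, "bc_category"),
                         n_perm = config$n_perm,
                         seed = sub_seed(config$seed, 4L))),
             grouping = "bc_category"),
      mutate(tidy(anosim(d, sample_groups(exp2, "season"),
                         n_perm = config$n_perm,
                         seed = sub_seed(config$seed, 5L))),
             grouping = "season"),
      mutate(tidy(permanova(d, sample_groups(exp2, "bc_category"),
                            n_perm = config$n_perm,
                            seed = sub_seed(config$seed, 6L))),
             grouping = "bc_category"),
      mutate(tidy(permanova(d, sample_groups(exp2, "season"),
                            n_perm = config$n_perm,
                            seed = sub_seed(config$seed, 7L))),
             grouping = "season"))
    readr::write_tsv(tests, file.path(out, "permutation_tests.tsv"))
    list(exp2 = exp2, tests = tests)
  })

  # 4. alpha diversity and site comparisons
  alpha <- stage("group_comparison", {
    adiv <- alpha_diversity(stats_out$exp2)
    readr::write_tsv(adiv, file.path(out, "alpha_diversity.tsv"))
    cmp <- pairwise_t_tests(adiv, "shannon", "site",
                            correction = config$correction)
    readr::write_tsv(tidy(cmp), file.path(out, "site_comparisons.tsv"))
    cmp
  })

  # 5. indicators
  ind <- stage("indicator_analysis",
               indicator_taxa(stats_out$exp2, ranks = "genus",
                              alpha = config$alpha,
                              score_threshold = config$lda_threshold,
                              seed = sub_seed(config$seed, 8L)))
  readr::write_tsv(ind, file.path(out, "indicator_taxa.tsv"))

  files <- sort(setdiff(list.files(out, full.names = TRUE), file.path(out, "manifest.json")))
  manifest <- list(
    package_version = as.character(utils::packageVersion("phyllobc")),
    seed = config$seed,
    parameters = list(n_taxa = config$community$n_taxa,
                      bc_effect_multiplier = config$community$bc_effect_multiplier,
                      season_effect_multiplier = config$community$season_effect_multiplier,
                      threshold_fraction = config$threshold_fraction,
                      connectivity = config$connectivity,
                      n_perm = config$n_perm),
    outputs = setNames(as.list(unname(tools::md5sum(files))), basename(files))
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
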