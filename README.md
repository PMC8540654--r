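# phyllobc

Leaf surfaces (the phylloplane) are continuously exposed to ambient air
pollution, and the microbial communities living there respond to it.
`phyllobc` implements the quantitative core of a two-year, six-site field
workflow on ivy (*Hedera helix*) leaves that links the two:

1. **Black-carbon (BC) particle counting** in two-channel microscopy
   z-stacks of leaf-wash suspensions. BC particles emit in both a narrow
   second-harmonic generation channel and a broad autofluorescence channel,
   while autofluorescent debris emits in only one. The caller thresholds
   each channel at 0.1% below its stack-wide maximum
   (`I > 0.999 · max I`), takes the voxelwise AND of the two masks, counts
   3D connected components as particles, and converts the mean count over a
   sample's five z-stacks into particles per gram of leaf:

   `load = mean(count) / V_img · (V_susp · 10^12 µm³/mL) / m_leaf`

2. **Community analysis** of the associated phylloplane microbiome from ASV
   count tables: removal of shallow samples (< 500 reads) and chloroplast
   lineages; the `S(x) = log10(x + 1)` scaling followed by per-million
   even-depth normalisation; observed richness, Shannon `H = −Σ p_i ln p_i`,
   and rarefaction; Bray–Curtis dissimilarity
   `d(a,b) = Σ|a_i − b_i| / Σ(a_i + b_i)` with PCoA and NMDS ordination;
   ANOSIM (`R = (r̄_between − r̄_within)/(M/2)`) and one-factor PERMANOVA
   (pseudo-F, R²) with label-permutation p-values; LEfSe-style indicator
   taxa (Kruskal–Wallis screen at p < 0.05, ridge-regularised LDA effect
   size, log10 score ≥ 2); and site/category mean comparisons with
   Bonferroni or Benjamini–Hochberg correction.

A first-class **synthetic-data module** generates every input with the
statistical structure the analysis assumes — the 6-site × 8-round design
arithmetic, Dirichlet–multinomial communities with planted BC-category and
seasonal effects (BC larger, as observed in the field), z-stacks with
planted coincident particles plus single-channel confounders, and seasonal
pollution series — so the full pipeline is testable without any field data.

The package is tidyverse-shaped: results come back as tibbles, fitted
objects have `tidy()`/`glance()` methods, and `autoplot()` /
`plot_rarefaction()` / `plot_indicators()` produce ggplot figures.

## Worked example

```r
library(phyllobc)

# --- BC particle detection on a simulated z-stack pair ---------------------
zs <- simulate_zstack_pair(n_particles = 10, n_confounders = 5,
                           snr = 5, seed = 42)
detect_bc_particles(zs)
#> <particle_set> 10 particles (10 coincident voxels)

bc_load(counts = rep(10, 5), imaging_volume_um3 = imaging_volume_um3(zs),
        suspension_volume_ml = 8, leaf_mass_g = 2)$load_particles_per_g
#> [1] 6306242
```

All ten coincident particles are recovered and none of the five
single-channel confounders is counted — the AND step makes that impossible
by construction. The load says: 10 particles per imaging volume, scaled to
an 8 mL suspension and 2 g of washed leaves, is ≈ 6.3 × 10⁶ particles/g.

```r
# --- community analysis on the default synthetic experiment ----------------
sim <- simulate_community(seed = 1)
e <- remove_taxa_by_lineage(filter_samples(sim$experiment), "Chloroplast")
d <- bray_curtis(transform_counts(e))

anosim(d, sample_groups(e, "bc_category"), n_perm = 999, seed = 1)
#> <ANOSIM> R = 0.5669, p = 0.001 (999 permutations)
anosim(d, sample_groups(e, "season"), n_perm = 999, seed = 1)
#> <ANOSIM> R = 0.1297, p = 0.001 (999 permutations)
permanova(d, sample_groups(e, "bc_category"), n_perm = 999, seed = 1)
#> <PERMANOVA> pseudo-F = 11.42, R2 = 0.1078, p = 0.001 (999 permutations)

head(indicator_taxa(e, ranks = "genus", seed = 1), 3)
#> # A tibble: 3 × 6
#>   taxon     rank  rank_letter enriched_group kw_p_value lda_score
#>   <chr>     <chr> <chr>       <chr>               <dbl>     <dbl>
#> 1 Genus_083 genus g           bcM              1.61e-28      4.94
#> 2 Genus_145 genus g           bcL              2.19e-28      4.25
#> 3 Genus_131 genus g           bcL              1.73e-29      4.22
```

Both groupings are significant, but the BC-category effect (R = 0.57) is
several times the seasonal one (R = 0.13) — the ordering the simulator
plants and the field study observed. The indicator table lists genera
enriched in one BC-load category with their Kruskal–Wallis p and LDA log10
score (≥ 2 by default).

`run_pipeline(pipeline_config(seed = 1))` chains
simulate → detect → transform → ordinate → test → indicators end-to-end and
writes TSV outputs plus a checksummed JSON manifest, identical for
identical seeds.

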