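---
title: "Methods: BC particle detection and phylloplane community statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: BC particle detection and phylloplane community statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyllobc)
```

`phyllobc` re-implements, as tested and reusable functions, the
quantitative chain of a field workflow that relates ambient air pollution
to leaf-surface (phylloplane) microbial communities. This vignette explains
the models and procedures, the parameters that matter, what the synthetic
data do and do not emulate, and the numerical choices made where the design
was genuinely open.

## Study design arithmetic

`study_design()` encodes the sampling campaign: six sites in three
phylloplane BC-load categories (`bcL`: DM, DW; `bcM`: HGa, HGb; `bcH`:
HKa, HKb), eight seasonal sampling rounds (two annual cycles of
autumn/winter/spring/summer, derived from the round index), 80 leaves per
site and round pooled into four metabarcoding samples, and 10 leaves per
site and round washed into two suspensions imaged as five z-stacks of 35
slices. `enumerate_design()` expands these counts into exact totals (e.g.
3840 metabarcoding leaves, 192 pooled samples, 96 BC suspensions, 175
slices per sample); these products are used directly as test oracles.

## BC particle detection

The detector mirrors a coincidence caller for the non-incandescent
white-light emission of BC particles under femtosecond-pulsed
illumination, observed simultaneously in a narrow second-harmonic channel
and a broad autofluorescence channel:

1. **Relative thresholding** (`threshold_channel()`): voxels with
   `I > (1 - f) · max(I)` are retained, with `f = 0.001` ("0.1% below the
   highest intensity"). The maximum is taken over the whole 3D stack of a
   channel, not per slice, and the comparison is strictly greater. Because
   the threshold is relative, the mask — and every downstream count — is
   invariant to positive rescaling of the channel. A channel with no
   dynamic range (all voxels equal, including all-zero) has no peaks to
   call and returns an empty mask with a warning; this is the only input
   on which the "fraction below maximum" rule is not meaningful.
2. **Coincidence** (`coincidence_particles()`): the two masks are combined
   by voxelwise AND, so emission present in only one channel —
   autofluorescent debris, pollen, cell material — cannot contribute a
   detection under any parameter setting. The AND requires identical
   voxels; no tolerance radius is applied, because the channels are
   acquired co-registered.
3. **Particle formation**: a particle is a 3D connected component of the
   coincident mask. 26-connectivity is the default (6 and 18 are flags);
   components rather than raw voxel counts are reported because the
   workflow's output is a number of particles. Labelling uses a sparse
   union-find over the thresholded voxels; tests compare it against an
   independent flood-fill on small stacks.
4. **Load conversion** (`bc_load()`): the mean count over a sample's five
   stacks is divided by the imaging volume (default geometry
   425.1 × 425.1 × 35.1 µm³), scaled to the full leaf-wash suspension
   (1 mL = 10¹² µm³) and divided by the washed leaf mass. The suspension
   volume is not part of the original description; it is an explicit,
   documented parameter with a default of 8 mL chosen as a plausible
   bench-scale wash volume, and flagged as arbitrary. The mean is the
   protocol's reducer; a median option is exposed.

`category_fold_change()` averages per-site mean loads within category and
reports ratios for all ordered category pairs; with the published per-site
means (`reference_bc_loads()`), the high/low contrast is ≈ 6.5-fold and
medium/low ≈ 2.8-fold, inside the reported 2–7-fold band.

## The z-stack simulator and what "perfect recovery" means

`simulate_zstack_pair()` plants 3D Gaussian blobs (σ = 1 voxel) at
rejection-sampled centres with a minimum Chebyshev separation of 5 voxels,
on a clipped-Gaussian background (mean 10, SD 2 intensity units). Three
deliberate design properties make detector validation exact rather than
statistical:

- all planted blobs share one exact peak intensity, `snr ×` the background
  mean, so the stack-wide maximum equals every blob peak;
- blob profiles are composited over the background with a voxelwise
  maximum, not added, so peaks are not perturbed by noise;
- background is clipped strictly below 0.999 × the peak.

Under these conditions the 0.1% relative threshold provably selects
exactly the peak voxel of every planted blob and nothing else, so the
planted count is recovered exactly and confounders are rejected exactly,
replicate after replicate. Real acquisitions have shot noise on the peaks,
spectral bleed-through and variable particle brightness; the simulator
deliberately idealises these away, so passing recovery tests demonstrates
the correctness of the thresholding/coincidence/labelling logic, not
field-condition robustness. The default simulated stack is 64 × 64 × 35
voxels — the axial depth mirrors the 35-slice acquisition while the
lateral extent is downscaled for speed; the voxel size default keeps the
425.1 × 425.1 × 35.1 µm³ volume of the instrument geometry.

## The community simulator

`simulate_community()` draws one sample per site × round × pool cell.
Expected relative abundances start from a common log-normal baseline
(meanlog 0, sdlog 1.5 — a realistically skewed rank-abundance curve over
the default 300 taxa). Ten percent of taxa are BC-effect taxa whose
expectation is multiplied 8-fold in their assigned category; ten percent
are season-effect taxa multiplied 3-fold in their assigned season. The BC
multiplier deliberately exceeds the seasonal one, encoding the field
observation that BC-load groupings separate communities more strongly than
seasons. Compositions are Dirichlet with concentration
`dispersion × expected proportions` (default 200, giving amplicon-like
overdispersion), and counts are multinomial at a library size uniform in
5000–20000 reads, the order of magnitude of the study's per-sample depths.
Two host-plastid ("Chloroplast") taxa are included by default so the
lineage filter is exercised end-to-end. Setting both multipliers to 1
yields exchangeable samples, the null used for calibration tests. The
generator does **not** emulate sequencing error, chimeras, taxonomic
misassignment, or compositional correlations between taxa; conclusions
from passing tests are about the statistics pipeline, not about those
artefacts.

`simulate_pollution_series()` adds a per-site sinusoidal seasonal
component to reference site means with Gaussian noise truncated at zero.
Phases encode the observed seasonality — BC and NO₂ peaking in winter,
particulate fractions in late winter/early spring, O₃ in summer
(anti-phased with NO₂). Defaults come from the published two-year site
means.

## Community statistics

Filtering drops samples with fewer than 500 reads (strictly less) and taxa
whose lineage contains "Chloroplast" at any rank, case-insensitively. The
beta-diversity transform is `S(x) = log10(x + 1)` per cell followed by
closure of each sample to 10⁶ (asserted to 1e-9 relative in tests); beta
diversity is computed on this transformed matrix, matching a workflow that
scales and normalises *before* measuring dissimilarity.

- **Shannon H** uses the natural logarithm (the vegan convention; the
  workflow's source is silent on the base), with a `base` argument.
- **Rarefaction** subsamples without replacement; its mean curve is tested
  against the exact hypergeometric expectation
  `Σᵢ (1 − C(N−nᵢ, d)/C(N, d))`.
- **Bray–Curtis** is `Σ|aᵢ−bᵢ| / Σ(aᵢ+bᵢ)`; the triangle inequality is not
  asserted anywhere because Bray–Curtis does not satisfy it in general.
- **PCoA** eigendecomposes the Gower double-centred matrix; coordinates
  are eigenvectors scaled by √λ for the k largest positive eigenvalues.
  Negative eigenvalues (expected for Bray–Curtis) are reported untouched —
  no Cailliez/Lingoes correction — and `k` is reduced with a warning when
  fewer positive eigenvalues exist.
- **NMDS** minimises Kruskal stress-1 by monotone regression using vegan's
  engine behind the package's `nmds()` surface, with 20 random restarts,
  300 iterations and the engine's convergence tolerances; the best start
  is kept and stress and convergence are reported. A fixed seed makes the
  result reproducible.
- **ANOSIM** ranks all n(n−1)/2 dissimilarities jointly (mid-ranks on
  ties) and computes `R = (r̄_b − r̄_w)/(M/2)`. The statistic reported is
  the standard R in [−1, 1]; field reports sometimes label ANOSIM output
  "R²", a naming discrepancy this package documents but does not adopt.
- **PERMANOVA** is one-factor only (the workflow tests single groupings):
  `SS_total = Σ d²/n`, within-group sums per group, pseudo-F and
  R² = SS_between/SS_total. On Euclidean distances it reduces exactly to
  classical one-way ANOVA, which the tests exploit as an oracle.
- **Permutation p-values** include the observed statistic,
  `p = (1 + #{T* ≥ T})/(1 + n_perm)`, so p = 0 is impossible; an `exact`
  mode enumerates all label permutations for small n and is tested against
  an independent recursive enumeration.

## Indicator analysis

`aggregate_to_rank()` sums ASV counts by rank label (unclassified entries
pool under `unclassified_<nearest labelled parent>`) and closes each
sample to per-million. The screen is a per-taxon Kruskal–Wallis test
(`stats::kruskal.test`, tie-corrected) at p < 0.05; constant taxa have no
defined p and are excluded with a note. Candidates are scored by a
bootstrap LDA effect size: 30 rounds, 2/3 of each class per round, a
ridge-regularised discriminant (ε = 10⁻⁶ relative to the mean within-class
variance) fitted jointly on all classes; the per-feature effect per class
pair averages the absolute between-class mean difference with the
discriminant-axis displacement attributed to the feature, the pairwise
maximum is taken, effects are averaged over bootstraps, and the score is
the log10. Enrichment is assigned one-vs-rest by the highest class mean.
The published LEfSe subclass (pairwise within-class Wilcoxon) step is
omitted — the design defines no subclasses. Reported rows satisfy
`p < 0.05` **and** `score ≥ 2` exactly as filtered; the unfiltered scores
stay retrievable.

A known limitation, shared with the original effect-size approach: the
score threshold of 2 corresponds to a 100-per-million effect, while the
sampling noise of a moderately abundant taxon at realistic sequencing
depth already produces apparent effects of that order once a taxon has
passed the significance screen. Specificity at threshold 2 is therefore
weak for abundant taxa — planted indicators reliably outrank null taxa
(the property the tests assert), but a null-free report cannot be
guaranteed on overdispersed count data.

## Group comparisons

Site/category mean comparisons use Welch two-sided t tests for every
unordered pair (pooled-variance by flag; the workflow's source says only
"t-tests"), corrected by Bonferroni or Benjamini–Hochberg via
`stats::p.adjust`, plus classical one-way ANOVA. Tests are pooled across
sampling rounds. `significance_letters()` encodes, per site, the set of
sites it differs from at adjusted p < 0.05 as the superscript letters
u…z in fixed site order, the convention of the field summary table.

## Pipeline, formats, determinism

`run_pipeline()` chains the stages under a single master seed from which
per-stage seeds are derived; identical configurations give byte-identical
outputs and therefore identical md5 checksums in the JSON manifest. Tables
travel as UTF-8 TSV (human-diffable), stacks as per-channel multi-page
32-bit TIFF (written rescaled to [0, 1], which the scale-invariant
detector ignores), configurations as YAML with a lossless round-trip.
Failures abort with a stage-tagged error and retain partial outputs. The
default pipeline images a small subset of suspensions (6 samples × 5
stacks); the simulators are cheap enough that the statistical stages run
on the full 192-sample design.

## Problem sizes used in validation

The shipped validation suite runs at desk scale, chosen once as realistic
exercise sizes for the methods: detector recovery on 50 replicate stacks
of 64 × 64 × 35 voxels (10 particles + 5 confounders, snr 5); null
calibration of ANOSIM/PERMANOVA on 200 replicate 16-sample instances with
199 permutations, checked against uniformity by a Kolmogorov–Smirnov test
at α = 0.01; BH false-discovery control over 500 replicate six-group
nulls; and the BC-versus-season effect ordering over 50 replicates of the
full 192-sample default community. The same quantities are recomputed by
`scripts/acceptance.R`.
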