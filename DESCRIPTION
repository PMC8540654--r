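Package: phyllobc
Title: Phylloplane Black Carbon Load and Leaf Microbiome Community Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies black carbon (BC) particle load on leaf surfaces from
    two-channel microscopy z-stacks by coincidence detection (per-channel
    relative thresholding, cross-channel voxel overlap, 3D connected-component
    particle counting, conversion to particles per gram of leaf), and analyses
    the associated phylloplane microbial communities: read-count filtering,
    chloroplast removal, log/per-million abundance transforms, alpha diversity
    and rarefaction, Bray-Curtis ordination (PCoA and NMDS), ANOSIM and
    PERMANOVA permutation tests, LDA-effect-size indicator taxa, and
    site/category mean comparisons with multiplicity correction. Ships a
    synthetic-data module (study design arithmetic, Dirichlet-multinomial
    community simulator, planted-particle z-stack simulator, seasonal
    pollution series) so the full pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    readr,
    tiff,
    vegan
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
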