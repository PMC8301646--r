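Package: phenodrought
Title: Image-Based Drought Phenotyping of Controlled-Environment Plant Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for controlled-environment drought phenotyping
    from multi-view RGB plant images: colour-space segmentation of plant from
    background with green/senescent tissue classification, 2-D digital shape
    traits (estimated shoot biomass, convex hull area, caliper length,
    minimum-area rectangle, bounding box), field-capacity-based watering
    schedules and water-loss traits, drought tolerance indices (YI, GMP, MP,
    TOL, STI and trait ratio indices), best linear unbiased estimates of
    genotype growth curves, and k-means classification of genotypes into
    drought-tolerance clusters. Includes a synthetic-data module that renders
    multi-view plant silhouettes with pixel-level ground truth and simulates
    replicated glasshouse experiments and pot-weight logs, so the full
    pipeline is testable end to end without proprietary imaging data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    grDevices,
    tibble,
    tidyr,
    withr
Suggests:
    mclust,
    optparse,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
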