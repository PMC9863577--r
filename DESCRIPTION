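Package: rarebiome
Title: Biogeography of Abundant and Rare Taxa in Microbial Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for comparative biogeography of abundant
    and rare taxa in amplicon-based microbial community surveys. Classifies
    OTUs into six occupancy-abundance categories (always/conditionally
    abundant, always/conditionally rare, moderate, conditionally rare and
    abundant), computes alpha/beta diversity and Levins niche breadth,
    fits distance-decay relationships and Mantel / partial Mantel tests,
    screens environmental predictors by variance inflation, runs db-RDA
    with forward selection and variation partitioning, quantifies community
    assembly with the nearest taxon index (NTI) and the normalized
    stochasticity ratio (NST), and infers Spearman co-occurrence networks
    with module detection and module-environment regressions. Includes a
    synthetic community generator with known assembly regimes for
    ground-truth validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    edgeR,
    geosphere,
    igraph,
    picante,
    stats,
    utils,
    vegan
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
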