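Package: phosgo
Title: Contrast-Based GO Enrichment Analysis for Phosphoproteome Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies Gene Ontology terms specifically enriched in a
    phosphoproteome sample by contrasting the sample not only against the
    genome but also against a phosphoproteome reference set. Builds
    experimental, predicted and union phosphoproteome references from gene
    lists and per-site predictor scores (max-aggregated to gene scores,
    thresholded at a resampled Youden-optimal cutoff), runs parent-child
    Fisher over-representation tests with Benjamini-Hochberg control,
    classifies terms by their binary significance pattern across
    comparisons, calls sample-specific terms, and characterises them by
    GenRatio and a Wang semantic-similarity layout. Includes a seeded
    synthetic-scenario generator (toy GO DAGs, annotation maps, bimodal
    score tables, planted enrichment) so the full strategy is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    igraph,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
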