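Package: pdxscreen
Title: Pharmacologic Profiling of PDX-Derived Tumor Cell Screens
Version: 0.1.0
Authors@R: person("PDTC", "Screening Group", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: End-to-end analysis of high-throughput drug viability screens
    run on patient-derived xenograft (PDX) tumor cells in 384-well plates:
    normalization of raw luminescence to fraction-affected against on-plate
    DMSO controls, robust cascade dose-response fitting (four-parameter
    logistic by iteratively reweighted least squares with a linear
    fallback), AUC and IC50 summarization, plate quality control (Z-prime,
    minimum significance ratio), bidirectional hierarchical clustering of
    AUC profiles with inactive/selective/pan-active drug classes,
    subtype-selectivity ANOVA, pharmacogenomic association testing with
    Sidak correction, single-sample GSEA pathway scoring, and
    pharmaco-transcriptomic correlation screens. Includes a synthetic
    screen generator with planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
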