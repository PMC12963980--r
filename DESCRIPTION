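Package: svgagg
Title: Ensemble Aggregation for Spatially Variable Gene Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies spatially variable genes (SVGs) in spatially resolved
    transcriptomics by aggregating the per-gene results of several detection
    methods instead of trusting any single one. Three ensemble strategies are
    provided: inverse-rank aggregation, Cauchy combination of p-values with
    Benjamini-Yekutieli correction, and a permutation-negative-control
    procedure that augments the expression matrix with spatially shuffled
    artificial genes and picks a selection-frequency threshold by minimising
    a penalised false-discovery-proportion proxy. The package ships
    lightweight built-in detectors (permutation Moran's I, a spatial
    covariance screen), adapters for result tables produced by external SVG
    tools, a synthetic data generator with planted hotspot, streak, gradient
    and curve patterns under Poisson, zero-inflated Poisson, negative
    binomial and zero-inflated negative binomial count models, and a
    benchmarking harness (confusion metrics, AUC, empirical FDR, quality
    scores, parameter sweeps).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    ape,
    fgsea,
    optparse,
    pROC,
    purrr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
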