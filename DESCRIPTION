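Package: coldnbs
Title: Network-Based Statistics for Affect-Coupled Changes in Brain
    Connectivity
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: End-to-end analysis of pre/post intervention resting-state
    ROI-to-ROI functional connectivity and its coupling with changes in
    self-reported positive and negative affect (PANAS). Provides a
    synthetic-cohort generator with planted connectivity effects, BOLD
    time-series denoising (motion/outlier flagging, aCompCor nuisance
    regression, band-pass filtering, frame censoring, QC-FC diagnostics),
    weighted Fisher-z connectivity matrices, edge-wise general linear
    models with affect-change covariates, network-based statistic (NBS)
    component inference with permutation family-wise error control and
    cluster-forming threshold sweeps, and the accompanying behavioural
    statistics (mixed-effects PANAS models, signed-rank tests with
    default-prior Bayes factors, physiological summaries).
License: MIT
Encoding: UTF-8
Imports:
    emmeans,
    ggplot2,
    igraph,
    jsonlite,
    lme4,
    lmerTest,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
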