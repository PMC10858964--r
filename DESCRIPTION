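Package: stemiProfiles
Title: Blood Gene Profiles and Measurement Time Cut-Offs for STEMI and
    NSTEMI
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Integrates multi-study blood gene expression data with
    literature-derived gene evidence to build high-score gene profiles
    that distinguish ST-elevation from non-ST-elevation myocardial
    infarction. Implements mean-difference gene folds on merged,
    batch-harmonized log-scale expression matrices, a three-layer
    evidence score (experiment, expression, final), percentile-based
    selection of high- and low-fold genes, score-weighted gene network
    assembly, hypergeometric over-representation enrichment, and a
    sigma-metric (total allowable error) procedure that turns repeated
    CV-sized shifts of a fold profile into a time cut-off for measuring
    the profile after myocardial infarction. A synthetic-data generator
    with planted fold effects makes every stage testable without any
    download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
biocViews: GeneExpression, DifferentialExpression, Microarray,
    NetworkEnrichment, QualityControl
Config/testthat/edition: 3
RoxygenNote: 7.3.3
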