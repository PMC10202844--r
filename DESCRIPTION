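Package: txsplice
Title: Longitudinal Differential Expression and Splice-Variant Diversity
    for Transcript-Level RNA-seq
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis of transcript-level RNA-seq counts from two-group
    longitudinal designs in which expression differences are expected to
    peak mid-course and vanish at the endpoints. Implements filtering of
    low-count transcripts, observation-level precision weights estimated
    from the mean-variance trend, weighted linear modelling with a
    quadratic group-by-time interaction, empirical-Bayes variance
    moderation and per-contrast false discovery rates; a splice-variant
    diversity statistic based on per-sample expressed-isoform counts,
    per-timepoint Poisson regression, fixed-effect inverse-variance
    meta-analysis and a global distribution-shift test; and MCODE
    molecular-complex detection on a supplied gene-interaction network
    with density-based cluster admission rules. A seeded negative-binomial
    simulator generates transcript-level count data with the full
    statistical structure the pipeline assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    igraph
Suggests:
    testthat (>= 3.0.0),
    limma,
    metafor,
    e1071,
    jsonlite,
    withr
biocViews: RNASeq, DifferentialExpression, AlternativeSplicing,
    NetworkInference, Regression
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
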