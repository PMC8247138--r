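Package: microdyn
Title: Longitudinal Microbiome Turnover, Segmentation and Resilience Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for longitudinal 16S amplicon studies with repeated sampling
    of the same subjects, built around a SummarizedExperiment-based container
    for ASV count tables with per-sample subject, day, diet and phase
    annotation. Implements temporal beta-diversity series (within-subject
    turnover at consecutive timepoints and between-subject divergence per
    timepoint), nonparametric PELT change-point detection with an MBIC
    penalty, genetic-algorithm refinement of pooled change-point candidates
    under a mixed-model RMSE fitness, per-segment random-intercept inference
    with Satterthwaite degrees of freedom, persistence-based clustering of
    ASVs into stable and inconsistent fractions via dynamic time warping,
    bipartite subject-ASV network dynamics with formed/destroyed edge models,
    per-ASV driver selection and hypergeometric enrichment. A synthetic-data
    generator emulates the crewed-isolation study design (6 subjects, 15
    timepoints over 720 days) with planted change-points so the whole
    pipeline is testable without sequencing data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    ape,
    vegan,
    lme4,
    lmerTest,
    phyloseq,
    cluster,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    DESeq2,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
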