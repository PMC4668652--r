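Package: ssRPMM
Title: Semi-Supervised Recursively Partitioned Beta-Mixture Classification of
    CpG Island Methylation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds case/control methylation classifiers from Illumina
    450K-style beta values summarized at CpG-island level. Probe-level beta
    matrices are filtered, averaged over annotated autosomal CpG islands, and
    ranked by linear mixed-effects association with case status on the
    M-value scale. A recursively partitioned product-beta mixture model
    (RPMM) clusters subjects on the top-ranked islands, with the number of
    islands chosen by nested cross-validation and held-out samples assigned
    to latent methylation classes by an empirical Bayes posterior.
    Performance is quantified by confusion tables for case-heavy classes,
    exact and logistic odds ratios, and ROC/AUC with DeLong confidence
    intervals; classifier islands can be validated on paired tumor/normal
    data with Wilcoxon signed-rank tests under Benjamini-Hochberg FDR
    control. Includes a synthetic-cohort generator with planted latent
    classes for end-to-end testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    lme4,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: DNAMethylation, Classification, Clustering, Epigenetics,
    MethylationArray
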