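Package: ferroscreen
Title: Analysis Pipeline for Ferroptosis-Sensitivity Screens, Lipidomics and
    Drug-Sensitivity Selectivity
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Reusable, tested implementations of the computational analyses
    used to establish lineage-selective ferroptosis sensitivity in clear-cell
    carcinomas: pooled CRISPR resistance-screen hit calling (reads-per-million
    normalization, per-sgRNA enrichment against an empirical null, gene-level
    hit rules, cross-condition intersection), lipidomics summed-composition
    annotation parsing with polyunsaturated-lipid classification and
    differential-abundance analysis, dose-response four-parameter-logistic
    fitting with normalized area-under-curve statistics, and CTRP-style
    lineage-selectivity testing of drug-sensitivity matrices. Every stage is
    exercisable on synthetic data with planted ground truth generated by the
    package itself.
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
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
biocViews: CRISPR, Lipidomics, Pharmacogenomics, Software, StatisticalMethod
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
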