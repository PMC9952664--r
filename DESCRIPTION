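Package: growsel
Title: GWAS-Preselected Marker Panels for Genomic Selection in Livestock
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end toolkit for studying whether variants preselected
    by genome-wide association studies improve genomic prediction of
    quantitative growth traits in two-breed livestock populations.
    Implements phenotype standardisation to 100-kg equivalents, genotype
    quality control with exact Hardy-Weinberg testing, mixed-linear-model
    association scans via eigendecomposition of a VanRaden genomic
    relationship matrix, a BayesC Gibbs sampler with 1-Mb window
    genetic-variance partitioning, fixed-effect inverse-variance
    meta-analysis across breeds, pooling of significant variants into
    selection panels, and single-kernel and two-kernel GBLUP with
    AI-REML variance components evaluated by replicated cross-validation.
    A two-breed genotype/phenotype simulator with known truth supports
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
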