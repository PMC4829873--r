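Package: tagseq
Title: Trait-Associated Gene Detection for RNA-seq by Ordinary and Robust Regression
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects trait-associated genes (TAGs) in bulk RNA-seq experiments by
    regressing a continuous phenotype (e.g. BMI, milk yield) on TMM-normalized
    log2 counts-per-million gene expression, per gene, with optional covariate
    adjustment. Provides ordinary least-squares and Huber M-estimator robust
    fits (IRWLS with MAD scale, Wald-type inference), genome-wide scans with
    Benjamini-Hochberg adjustment, Shapiro-Wilk residual-normality screening,
    a permutation-based mock-comparison simulation that estimates the
    proportion of false discoveries as a function of biological-replicate
    count, and a negative-binomial synthetic-data generator with known TAG
    structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    optparse
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    MASS,
    edgeR,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
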