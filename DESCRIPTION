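Package: omniprs
Title: Gene-Set Polygenic Risk Scores Under an Omnigenic Background
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Leave-one-out cross-cohort polygenic risk score (PRS) analysis for
    gene sets in multi-study case-control panels. Provides a liability-threshold
    synthetic cohort generator with an omnigenic effect-size background and
    optional core-gene-set enrichment, PLINK-style text I/O and genotype quality
    control, sliding-window LD pruning, a fast per-SNP logistic training GWAS,
    gene-set-restricted PRS with in-training p-value threshold selection, nested
    logistic-regression evaluation (likelihood-ratio tests, Nagelkerke pseudo
    R-squared), Stouffer's Z meta-analysis across held-out cohorts, an
    experiment-wise phenotype-permutation null, and random genic/non-genic SNP
    set analyses that estimate the "floor" of variance explained expected under
    an omnigenic architecture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    yaml,
    withr,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
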