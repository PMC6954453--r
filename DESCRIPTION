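Package: polygxe
Title: Polygenic Tests for Gene-Environment Interaction in GWAS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects polygenic gene-environment (G x E) interaction from
    genome-wide SNP data when no external GWAS weights are available.
    Implements the adaptive combination of Bayes factors (ADABF) test:
    per-SNP Wakefield Bayes factors for SNP x E interaction coefficients,
    cumulative ordered-score statistics calibrated by a multivariate-normal
    resampling null, an overall min-P test, and a resampling false discovery
    rate for pinpointing individual interacting SNPs.  Also provides two
    internally weighted genetic risk score comparators (GRS-M, weighted by
    marginal SNP effects, and GRS-I, weighted by interaction effects with
    sample splitting), single-marker scans with Bonferroni and
    Benjamini-Hochberg control, PLINK 1 binary genotype input with quality
    control and windowed variance-inflation-factor pruning, and a simulation
    harness for type I error, power, sensitivity and positive predictive
    value studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
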