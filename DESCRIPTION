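Package: tsrf
Title: Two-Stage Quality-Based Random Forests for Case-Control SNP Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Random-forest classification and feature ranking for very
    high-dimensional case-control genotype (SNP dosage) and gene-expression
    data. Informative features are first separated from noise by comparing
    replicated Gini importance scores against permuted shadow features with a
    one-sided Wilcoxon rank-sum screen, then partitioned into highly and
    weakly informative groups by a chi-squared association test; trees are
    grown on candidate subspaces sampled proportionally from both groups so
    that every node sees informative features. Includes a plain
    random-forest baseline sharing the same tree engine, a synthetic
    case-control genotype generator, out-of-bag strength/correlation
    diagnostics with the c/s^2 generalization-error bound, and a stratified
    cross-validation harness.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
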