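Package: mrkit
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) with GWAS
    summary statistics: instrument selection with greedy linkage-disequilibrium
    clumping and instrument-strength diagnostics, allele harmonization with
    palindromic-variant filtering, inverse-variance-weighted, MR-Egger,
    weighted-median and mode-based causal estimators with heterogeneity and
    leave-one-out diagnostics, MR-PRESSO outlier detection by residual-sum
    resampling, pairwise multivariable MR with conditional instrument-strength
    tests, a multi-exposure screening pipeline with Bonferroni control and
    power diagnostics, and a summary-statistic simulator with configurable
    horizontal pleiotropy for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
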