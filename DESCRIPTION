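Package: mrpipe
Title: Two-Sample Mendelian Randomization Pipelines for GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A complete two-sample Mendelian randomization (MR) toolkit for
    GWAS summary statistics: reading and validating association tables,
    allele harmonization (including palindromic-variant policies), greedy
    LD clumping and instrument selection, variance explained on observed and
    liability scales, the Wald ratio / inverse-variance weighted / weighted
    median / MR-Egger estimators with Cochran Q heterogeneity, a
    simulation-based global pleiotropy and outlier test with outlier-corrected
    re-estimation, multivariable MR for cluster-weighted exposures,
    Benjamini-Hochberg multiplicity control across an exposure-by-outcome
    analysis grid, bidirectional analyses, and a seeded synthetic
    summary-statistics generator with known causal truth so every stage is
    verifiable by parameter recovery.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
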