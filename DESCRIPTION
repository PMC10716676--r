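Package: cismr
Title: Cis-Mendelian Randomisation for Drug-Target Effects from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for drug-target cis-Mendelian randomisation from GWAS
    summary statistics: reading and harmonising two-sample summary data with a
    signed linkage-disequilibrium (LD) matrix, cis-eQTL instrument selection
    with greedy LD pruning and instrument-strength diagnostics, Wald-ratio
    estimation meta-analysed by correlated-instrument inverse-variance
    weighting with multiplicative random effects, dose-equivalent scaling,
    Benjamini-Hochberg false-discovery-rate correction, Bayesian
    colocalisation via per-variant approximate Bayes factors, two-step cis-MR
    adjustment for pleiotropic mediator pathways, and a seeded generator of
    synthetic two-sample summary statistics for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
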