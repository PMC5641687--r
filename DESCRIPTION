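Package: genefactor
Title: Latent Genetic Factor Association Models for X-Linked SNPs and
    Longitudinal Binary Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Categorical structural equation modelling of X-linked SNP
    genotypes and longitudinal binary questionnaire items.  Provides
    two-stage polychoric and tetrachoric correlation estimation with
    asymptotic variances, a diagonally weighted least squares (DWLS) fitting
    engine with mean- and variance-adjusted test statistics, longitudinal
    measurement invariance ladders (configural, strong, strict), latent
    difference score models, latent genetic factor association tests with
    Benjamini-Hochberg false discovery rate control, liability-threshold
    cohort simulation for sex-stratified X-linked designs, and Monte Carlo
    power analysis comparing latent-variable and single-SNP association
    approaches.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    yaml,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mvtnorm,
    vcfR,
    jsonlite,
    withr
Config/testthat/edition: 3
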