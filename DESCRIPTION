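Package: adipomet
Title: Observational and Mendelian Randomization Profiling of Adiponectin
    and the Systemic Metabolome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-arm analysis pipeline contrasting conventional
    multivariable regression with two-sample Mendelian randomization for
    the association between circulating adiponectin and a correlated
    panel of metabolic measures. Provides a synthetic multi-study data
    generator with a latent adiposity/insulin-resistance confounder and
    cis-instrument genotypes, inverse rank-based normal transformation of
    covariate-adjusted metabolites, a principal-component estimate of the
    effective number of independent tests for Bonferroni correction,
    per-study regression and Wald-ratio/inverse-variance-weighted
    instrumental-variable estimation, DerSimonian-Laird random-effects
    pooling with heterogeneity statistics, and Z-test comparison of the
    two arms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    utils
Suggests:
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
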