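Package: leafspectra
Title: Leaf Trait Variation, Production-Tolerance Spectra and Multimodel
    Driver Attribution for Invasive Plant Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing leaf functional trait variation and the leaf
    production/stress-tolerance spectrum across plant populations sampled in
    paired invaded/uninvaded plot surveys. Implements min-max phenotypic
    variation indices (PVI), max-normalised leaf production and
    stress-tolerance indices (LPI, LTI) and the paired-plot relative change
    metric; standardised major axis (model II) regression; one-way ANOVA with
    Tukey HSD compact letter displays; and an exhaustive all-subsets
    multimodel-inference engine (AICc ranking, Akaike weights, 95 percent
    cumulative-weight model averaging, summed-weight variable importance and
    grouped relative/per-capita contribution decomposition). A seeded
    synthetic-survey generator with a known linear trait-environment effect
    structure makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
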