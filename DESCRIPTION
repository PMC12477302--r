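Package: distylr
Title: Reciprocity, Inaccuracy and Factorial Trait Models for Distylous
    Populations Under Fire
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how disturbance (fire) affects the
    functioning of distyly. Implements the adaptive-accuracy (inaccuracy)
    reciprocity statistic between floral morphs, with its decomposition into
    maladaptive bias and imprecision and bootstrap uncertainty; a synthetic
    trait-table generator emulating a two-morph, two-area hierarchical
    sampling design; factorial generalized linear (mixed) trait models with
    type-II Wald tests, back-transformed marginal means and morph-conditioned
    contrasts; percent effect-size computation between group means; and
    nectar energetics conversions (Brix to sucrose equivalents to calories).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    dplyr,
    emmeans,
    generics,
    ggplot2,
    glmmTMB,
    jsonlite,
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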