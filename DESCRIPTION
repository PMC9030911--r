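Package: tripletrct
Title: Matched-Triplet Randomization and Permutation Inference for
    Three-Arm Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and analysing three-arm randomized
    trials that assign treatment within propensity-score-matched triplets.
    Implements the four-step randomization (propensity model,
    baseline-adherence stratification, triplet matching, permutation
    assignment), effect estimation via contingency-table and logistic-regression
    odds ratios (unadjusted and covariate-adjusted), ratio-of-odds-ratios
    effect-modification analysis, triplet-level rerandomization
    (permutation) inference with Holm-Bonferroni multiplicity control,
    baseline balance diagnostics, and a synthetic trial generator with
    configurable arm effects and wave-wise attrition.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
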