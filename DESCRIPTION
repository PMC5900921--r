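Package: provdom
Title: Multidimensional Provider Performance Assessment with Dominance Criteria
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates multivariate multilevel (random-intercept) models for mixed
    continuous and binary performance dimensions with correlated provider-level and
    patient-level random terms, using Gibbs sampling with probit data augmentation.
    Empirical Bayes posteriors of provider effects are classified against a benchmark
    as dominant, dominated or non-comparable via simulated multivariate-normal orthant
    probabilities, alongside univariate and Bonferroni-corrected "confidence box"
    comparisons. Includes a two-stage residual inclusion correction for endogenous
    provider choice instrumented by patient-provider distance, and a synthetic-data
    generator emulating a hip-replacement provider profiling setting (skewed length of
    stay, patient-reported outcome score, waiting-time and readmission indicators)
    with configurable missingness and distance-driven selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    mvtnorm,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    optparse,
    withr
Config/testthat/edition: 3
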