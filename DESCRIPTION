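Package: cwmaxent
Title: Trait-Based Maximum Entropy Prediction of Species Relative Abundance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements the Community Assembly by Trait Selection (CATS)
    maximum entropy model: species relative abundances in a community are
    predicted as the maximum entropy distribution (relative to a prior)
    subject to community-weighted mean (CWM) trait constraints. Provides
    trait preprocessing (log transforms, nonnegative unit-variance scaling),
    a dual Newton solver with an Improved Iterative Scaling reference
    implementation, lambda (Lagrange multiplier) extraction and
    interpretation, Shipley-style permutation tests of model fit, backward
    and gradient-driven forward trait selection, linear mixed models
    relating CWM traits and lambda values to an environmental (water depth)
    gradient, and a synthetic community generator with known trait-based
    filtering for end-to-end validation. Tailored to macrophyte communities
    sampled along a water depth gradient but applicable to any
    plots-by-species abundance data with species-level traits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    lmerTest,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
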