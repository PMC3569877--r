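Package: parallelgrowth
Title: Multivariate Linear-Spline Multilevel Models for Parallel Growth Processes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits multilevel (mixed-effects) models with linear-spline time
    trajectories for two or more responses measured repeatedly on the same
    individuals, such as weight and mean arterial pressure across pregnancy.
    Temporal hypotheses about when changes in one process may relate to
    changes in another are expressed as zero-constraints on individual-level
    random-effect covariances and tested by likelihood ratio. Mutually
    adjusted regression coefficients among random effects (e.g. of later
    blood-pressure change on earlier weight gain) are derived from the fitted
    random-effect covariance matrix, with moment-based, delta-method and
    simulation-based standard errors. A structural-equation (latent growth
    curve) view of the same model is provided for moment-equivalence checks,
    together with a synthetic-data generator for unbalanced bivariate
    longitudinal designs.
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
    MASS,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    lme4,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
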