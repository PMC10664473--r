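Package: slopesim
Title: Sample Size and Simulation Tools for Trials Where Treatment Slows a
    Rate of Change
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Design and simulation toolkit for randomised trials whose
    outcome is a continuous measure of deterioration analysed with a
    random slopes mixed model. Provides a longitudinal trajectory
    simulator (linear and three non-linear mean shapes, three
    treatment-effect shapes), a constrained REML engine for the random
    slopes model, iterated-GLS fitting of three marginal models with
    unstructured covariance, a two-stage sample-size calculator driven by
    pilot or observational data, and a Monte-Carlo harness that measures
    power, type-I error and standard-error bias across scenario grids.
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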