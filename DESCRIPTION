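Package: fircompat
Title: Compatible Aboveground Biomass Models for Chinese Fir from LiDAR Tree Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits and compares allometric aboveground-biomass models for
    Chinese fir (Cunninghamia lanceolata) driven by LiDAR-derived tree height
    and crown diameter: four candidate base forms (logistic, linear,
    exponential, power), age-group dummy-variable power models with
    group-specific scale coefficients, and an additivity-constrained
    nonlinear seemingly unrelated regression (NSUR) system estimated by
    iterated feasible generalized least squares, in which predicted component
    biomasses (trunk, bark, branch, leaf) sum exactly to the predicted total.
    Includes a synthetic stand generator with correlated multiplicative
    component errors for testing the full pipeline, national-standard-style
    total-allometry and ratio disaggregation equations, evaluation metrics
    (R2, RMSE with the n-1 denominator, total relative error, AIC, BIC), and
    an end-to-end reproducible pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
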