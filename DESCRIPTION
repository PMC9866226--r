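Package: thermodev
Title: Temperature-Dependent Development Models for Arthropods
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits linear (degree-day and Ikemoto-Takai) and twenty classical
    non-linear temperature-development-rate models (Briere, Logan, Lactin,
    Kontodimas, Analytis, Sharpe-DeMichele and others) to stage-resolved
    development-time data of ectotherms. Provides bounded multistart
    Levenberg-Marquardt least-squares fitting, goodness-of-fit statistics
    (RSS, R2, adjusted R2, AIC), extraction of cardinal temperatures
    (lower threshold, optimum, upper threshold) by closed forms, grid search
    and root finding, thermal-constant estimation, degree-day phenology
    forecasting, and a synthetic-cohort generator for parameter-recovery
    testing. Ships a transcribed development-time table for the ladybird
    Stethorus gilvifrons reared on Tetranychus urticae as a worked dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
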