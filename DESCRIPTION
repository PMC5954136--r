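Package: titrate
Title: Interval-Timing Analysis for Temporal Bisection and Peak-Interval Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for rodent interval-timing experiments:
    pseudologistic psychometric fitting of temporal-bisection choice data
    (point of subjective equality and the gamma sensitivity parameter),
    molar peak-interval analysis with Gaussian-plus-ramp curve fitting
    (peak time, peak rate, width, coefficient of variation) and a temporal
    discrimination index, and single-trial low-high-low three-state
    change-point decomposition (start, stop, spread, state rates,
    initiation and suppression ratios, bracketed start-stop correlations).
    Includes a seeded generative model of both tasks, with optional
    stress perturbation, for parameter-recovery validation, plus
    event-log CSV input/output and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
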