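Package: kneesense
Title: Intraoperative Knee Load Sensing with Bayesian-Regularized Neural Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, calibration and evaluation pipeline for an
    instrumented tibial insert that measures contact load and centre of
    pressure during total knee replacement. Provides a synthetic forward
    model of a two-compartment strain-gauge sensor, the grid-based
    calibration protocol (load schedules, best-fit-curve extrapolation,
    min-max normalization, multiplicative noise augmentation), from-scratch
    Bayesian-regularized Levenberg-Marquardt training of small feed-forward
    regression networks, a three-point load-cell triangulation baseline with
    sensing-area classification, and the accuracy/precision/MSE evaluation
    protocol with group comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
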