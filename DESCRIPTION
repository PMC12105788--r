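Package: strucdisc
Title: Structural Discrepancy Assessment, History Matching and Bayes Linear
    Forecasting for Computer Simulators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying the structural (model) discrepancy of a
    computer simulator and propagating it through history matching and Bayes
    linear forecasting. Internal discrepancy is assessed by designed
    perturbation experiments on the simulator itself (jittered initial
    conditions, time-varying rate parameters), summarized by per-output bias
    and variance fields and their output-output correlation, and emulated over
    the input space by linear-regression emulators. External discrepancy is
    specified directly as nominal fractional or absolute standard deviations.
    Non-implausible input regions are found by iterative history matching with
    the maximum-implausibility criterion, and second-order (Bayes linear)
    adjustment transfers the discrepancy structure learned on historical
    outputs into improved forecasts of future outputs. The workflow is
    demonstrated end-to-end on a Lotka-Volterra predator-prey simulator with
    pseudo-observations generated from a stochastic Gillespie variant of the
    same system.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    lhs,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
NeedsCompilation: yes
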