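Package: attractorchoice
Title: Choice Hysteresis in Competitive Attractor Networks with Simulated
    Polarizing Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates a spiking winner-take-all attractor network performing
    a random-dot-motion choice task in continuous sessions, with transcranial
    direct current stimulation modeled as small constant transmembrane
    currents, and provides the complete behavioral and neural analysis
    pipeline for quantifying choice hysteresis (the tendency to repeat the
    previous choice): sequential logistic regression with a previous-choice
    term, indecision-point shifts, Weibull accuracy thresholds,
    decision-time regressions, prestimulus firing-rate bias measures, and
    the associated nonparametric tests. Includes a synthetic behavioral
    data generator so every analysis stage can be validated without running
    the network.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite,
    minpack.lm
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
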