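Package: clampdesign
Title: Model-Driven Design of Voltage-Clamp Protocols for hERG Channel Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation of hERG (Kv11.1) Markov gating models under arbitrary
    step/ramp voltage-clamp protocols, and automated synthesis of short,
    information-rich protocols by derivative-free optimisation of a suite of
    design objectives: local parameter sensitivity, first-order Sobol
    sensitivity, sampled-parameter output spread, two-model discrimination,
    phase-voltage-space coverage, and square-wave discrimination. Includes the
    four-state Beattie-type model (with its two-gate Hodgkin-Huxley
    equivalent), the five-state Wang-type model, matrix-exponential and
    adaptive ODE solvers, protocol file input/output, synthetic-data
    generation and sum-of-squares model fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    deSolve,
    lhs,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
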