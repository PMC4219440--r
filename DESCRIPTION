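Package: phosim
Title: Gaze-Contingent Simulation of Thalamic Prosthetic Vision for Reading Psychophysics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the visual experience of a thalamic (LGN) visual
    prosthesis wearer during a continuous-text reading task.  Generates
    eccentricity-scaled phosphene patterns from a center-weighted radial
    density profile calibrated against published electrode-count windows,
    renders gaze-contingent frames by Gaussian sample-and-splat filtering of
    rasterized MNREAD-style sentences, runs a four-phase trial state machine
    on a simulated clock with synthetic gaze traces, applies a second-order
    polynomial gaze-calibration correction, and scores reading accuracy,
    speed, and acuity (MNREAD and logistic-midpoint) in logMAR units,
    including the expected square-root scaling of acuity with phosphene
    count.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    stats,
    grDevices,
    graphics,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
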