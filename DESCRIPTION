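Package: ctcsim
Title: Simulation Toolkit for Unilateral Bone-Conduction Crosstalk Cancellation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools to design, estimate and evaluate unilateral crosstalk
    cancellation for bone-conduction hearing devices, entirely in simulation.
    Provides time-stretched-pulse (swept sine) impulse-response measurement by
    exact spectral deconvolution, Kirkeby frequency-dependent-regularization
    inverse filtering for transducer equalization, filtered-x LMS estimation of
    the crosstalk-compensation (CTC) filter, quantitative verification of the
    achieved cancellation at the error sensor, and the psychoacoustic
    evaluation machinery (2-down/1-up three-interval forced-choice staircases,
    bracketing audiometry, simulated listeners, occlusion-effect computation).
    A synthetic-head module generates plausible transcranial transfer paths so
    every stage runs without measurement hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    stats,
    tibble,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
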