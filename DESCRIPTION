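Package: minwave
Title: Simulation and Analysis of Min-Protein Pole-to-Pole Oscillations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A one-dimensional five-species reaction-diffusion model of the
    Escherichia coli Min system (cytosolic MinD-ADP/MinD-ATP and MinE,
    membrane-bound MinD and MinDE), integrated by an explicit finite-difference
    scheme with no-flux boundaries. Provides linear stability analysis of the
    uniform steady state for Hopf/Turing screening of kinetic rate constants,
    oscillation descriptors extracted from kymographs (period, the normalized
    gradient decay constant lambda_N, and the midcell-to-pole intensity ratio
    I_Ratio), a random-parameter screening pipeline, fluorescence-profile
    analysis algorithms (photobleaching correction, center fraction,
    two-sided exponential intensity-ratio estimation, biexponential snapshot
    correction), and synthetic-data generators with ground-truth records for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    deSolve
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
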