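Package: synclock
Title: Stochastic Circadian Oscillators in Multinucleate Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation and analysis of a transcription-translation
    negative-feedback circadian oscillator distributed over the nuclear
    compartments of a syncytial (multinucleate) cell. Provides an exact
    Gillespie stochastic simulation of the compartmentalized reaction
    network in which cytoplasmic proteins equilibrate across compartments
    while mRNAs stay local, the deterministic ODE counterpart with its
    analytic oscillation threshold, a spectral quality factor for rating
    limit-cycle regularity, and scripted experiments quantifying division
    of transcriptional labor between nuclei and the synchronizing effect
    of protein sharing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    graphics,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
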