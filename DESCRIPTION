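Package: wavesplit
Title: Eco-Evolutionary Wave Splitting in Cooperator-Defector Range Expansions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coupled reaction-diffusion models of cooperator-defector range
    expansions with an Allee effect and density-dependent frequency-dependent
    selection. Provides closed-form expansion, invasion and mixed-wave
    velocities and the exact bistable front profile; an explicit
    forward-time centered-space (FTCS) solver for the coupled two-allele
    system with front tracking and outcome classification; a spectral
    (Schroedinger potential well) predictor that decides whether a mixed
    wave splits into a pure-cooperator expansion wave followed by a defector
    invasion wave; an individual-based stochastic lattice simulator for
    stochastic wave splitting and waiting-time experiments; and reproducible
    experiment drivers (critical-density phase scans, transient-splitting and
    wave-acceleration runs).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
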