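Package: csdwave
Title: Reaction-Diffusion Simulation of Cortical Spreading Depression
    with Refractory-Period Modulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates cortical spreading depression (CSD) as a
    two-variable excitable medium on a 2D grid: extracellular potassium
    diffuses and reacts through a bistable cubic, and a lumped recovery
    variable imposes a refractory period.  Recovery inside a configurable
    "modulated area" can be slowed by a factor F applied only while the
    recovery variable is relaxing, which reproduces three propagation
    regimes for successive CSD waves: bypass of the modulated area at
    small F, slowed propagation at intermediate F, and spiral (re-entrant)
    waves after release of a transient conduction block.  Provides scenario
    presets for each regime, probe-trace recording, wave-event detection,
    regime classification, propagation-speed measurement, an F-sweep regime
    mapper, and deterministic text/TIFF export of field snapshots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    ggplot2,
    jsonlite,
    rlang,
    tibble,
    tidyr,
    yaml,
    generics,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    withr
Config/testthat/edition: 3
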