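Package: asnkin
Title: Kinetic Modeling and Parameter Estimation for Asparagine
    Synthetase Reaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for mechanistic kinetic analysis of the
    glutamine-dependent asparagine synthetase reaction. Represents
    biochemical reaction schemes as continuous Petri nets (species with
    clamped-concentration support plus mass-action reactions), compiles
    them to ordinary differential equation systems with conserved-moiety
    analysis, integrates them with stiff solvers, and estimates rate
    constants from time-course data with a derivative-free Hooke-Jeeves
    pattern search in log-parameter space. Ships the canonical wheat
    asparagine synthetase (TaASN1/TaASN2) model and a synthetic-data
    generator that emulates an HPLC activity assay, including linear
    peak-area calibration against amino-acid standards and replicate
    measurement noise, for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    xml2,
    withr
Config/testthat/edition: 3
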