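Package: pillartrap
Title: Critical-Pressure Modelling for Hydrodynamic Cell Trapping in
    Micropillar Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Toolkit for designing microfluidic pillar traps that capture
    deformable cells by size and stiffness.  Provides a closed-form
    power-law model of the critical escape pressure of a cell pressed
    against a rigid diamond-pillar gap, power-law regression over
    simulation sweeps with model-order comparison and validation
    statistics, a desk-scale neo-Hookean finite-element contact simulator
    with bisection search for the critical pressure, a depth-averaged
    Stokes/Brinkman solver for the carrier flow through a trapping unit,
    and cohort-level capture statistics, gap recommendations and
    operating-pressure curves for common tumor cell lines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    minpack.lm,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
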