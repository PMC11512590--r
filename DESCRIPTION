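Package: metafes
Title: Free Energy Surfaces from Metadynamics HILLS Files
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of metadynamics simulations from Plumed-format HILLS
    files. Reconstructs free energy surfaces by exact or fast
    precomputed-kernel Gaussian hill summation on periodic or open grids,
    detects local free-energy minima with basin assignment and
    population-weighted state free energies, tracks per-minimum free
    energies along the simulation as a convergence diagnostic, and
    estimates standard errors of free-energy differences by integrated
    autocorrelation analysis of basin-occupancy series. Ships an
    overdamped Langevin simulator on analytic model potentials that
    writes Plumed-dialect HILLS files for ground-truth benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
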