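Package: flickerspec
Title: Flicker Spectroscopy of Biomolecular Condensates and Vesicles
Version: 0.1.0
Authors@R:
    person("flickerspec", "developers", email = "flickerspec@example.org",
           role = c("aut", "cre"))
Description: Measures interfacial tension and bending rigidity of
    biomolecular condensates and vesicles from time-lapse confocal
    microscopy by flicker spectroscopy: difference-of-Gaussians object
    detection and memory-based tracking, sub-pixel radial boundary
    extraction, Fourier fluctuation spectra with base-shape correction,
    and fitting of the Helfrich-type thermal spectrum. Includes a
    synthetic fluctuating-droplet generator (spherical-harmonic
    equilibrium sampling rendered as confocal-like image stacks) so that
    every pipeline stage is testable by parameter recovery, plus a
    lexicographic Gaussian-process Bayesian optimizer for detection
    parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    rhdf5,
    stats,
    tools,
    utils,
    xml2,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
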