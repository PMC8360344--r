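Package: fflmpi
Title: Simulation and Filtered-Backprojection Reconstruction for a
    Single-Sided Field-Free-Line Magnetic Particle Imaging Scanner
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Forward simulator and image-reconstruction pipeline for a
    single-sided field-free-line (FFL) magnetic particle imaging (MPI)
    scanner.  Computes the magnetic fields of the racetrack selection
    coils and the planar drive and receive coils from the Biot-Savart
    law, calibrates the FFL trajectory so the line can be commanded to
    any in-plane position at a fixed height, synthesizes the harmonic
    voltage signal of superparamagnetic iron oxide nanoparticle tracers
    under the adiabatic Langevin magnetization model, assembles
    sinograms over stepped shift/rotation scans, and reconstructs 2D
    tracer-distribution images by filtered backprojection with
    apodized ramp filters.  Includes phantom generators, contrast and
    signal-to-noise metrics, and end-to-end study runners.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    png,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
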