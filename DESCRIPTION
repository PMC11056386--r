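Package: grom
Title: Simulation and Quantitative Phase Reconstruction for Gradient
    Retardance Optical Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative phase imaging (QPI) with phase-shifted
    differential interference contrast (DIC) microscopy. Generates
    ground-truth optical phase phantoms (beads, flats, random fields),
    simulates shear-interferometric bias series under a programmable
    retarder schedule with diffraction blur and shot noise, demodulates
    the series into gradient-phase maps by 4-step and N-step
    phase-shifting interferometry, and integrates the gradients into
    quantitative phase images by Fourier (Hilbert-kernel) inversion, with
    cumulative-sum and Wiener-deconvolution baselines, rolling-ball
    background correction, and validation metrics (robust peak phase,
    Gaussian-fit FWHM, radially averaged profiles).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    tiff,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
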