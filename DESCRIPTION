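Package: thermotomo
Title: Three-Dimensional Thermal Tomography with Physics-Informed Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and learning toolkit for steady-state thermal
    tomography of cylindrical phantoms. Provides a finite-difference
    Poisson solver with convective (Robin) boundary conditions for
    phantoms containing cylindrical heat sources, orthographic sinogram
    synthesis of the observable surface temperature, a self-contained 3D
    convolutional residual autoencoder that reconstructs the internal
    excess-temperature field from sinogram stacks, noise-aware and
    physics-informed training regimes, and a volumetric evaluation suite
    (SSIM, PSNR, MSE, NMSE, MAE, Dice, IoU, globally and in a dilated
    region of interest) together with depth-resolved error analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr,
    optparse
Config/testthat/edition: 3
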