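Package: detrunc
Title: Unsupervised Removal of CT Truncation Artifacts via Polar-Domain
    Feature Disentanglement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for simulating and removing truncation (cupping)
    artifacts in fan-beam computed tomography. Provides a seeded ellipse
    phantom generator, a fan-beam projector with symmetric sinogram
    truncation and filtered backprojection, polar-coordinate resampling
    that maps cup-shaped artifacts to line-shaped ones, an unpaired
    image-translation network with a shared encoder that implicitly
    disentangles artifact and content features in latent space, classical
    comparators (sinogram extrapolation and total-variation constrained
    iterative reconstruction), and PSNR/SSIM/radial-profile evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    png
Config/testthat/edition: 3
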