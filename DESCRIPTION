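Package: fodfsr
Title: Super-Resolution of Fiber Orientation Distributions from Diffusion MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Patch-based super-resolution of fiber orientation distribution
    functions (fODFs) estimated from single-shell diffusion MRI by constrained
    spherical deconvolution. Provides a real symmetric spherical-harmonic basis
    with the probability normalization used for fODF-valued images, a synthetic
    single-shell phantom simulator with Rician noise and block-averaging
    downsampling, a constrained spherical deconvolution fitter, a dense
    neural-network upsampler mapping 3x3x3 low-resolution neighborhoods of SH
    coefficients to the 2x2x2 high-resolution block of the central voxel,
    spline-interpolation baselines on the matching half-voxel-offset grid, and
    an evaluation stack: fODF peak extraction, angular earth mover's distance,
    generalized anisotropy, per-coefficient similarity metrics, and
    method-comparison tallies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    generics,
    ggplot2,
    pracma,
    Rcpp,
    RNifti,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
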