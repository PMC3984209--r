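Package: sidefire
Title: Light Delivery Modeling and Activation-Map Analysis for Side-Firing
    Fiber Optogenetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Voxel Monte-Carlo simulation of photon transport in scattering
    brain tissue for side-firing and axial optic-fiber sources, with
    Henyey-Greenstein scattering, absorption weighting and Russian roulette.
    Thresholds the resulting fluence maps at the channelrhodopsin-2
    half-maximum irradiance to estimate optogenetically activated tissue
    volumes and their spatial overlap under fiber rotation and translation.
    Also provides a synthetic intrinsic-optical-imaging trial generator with
    a gamma-variate hemodynamic response and the matching activation-map
    pipeline: trial averaging, pre-stimulus normalization, Gaussian spatial
    filtering, pixelwise Welch t-maps, significant-area quantification and
    intensity-response curve fits.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    tiff,
    RNifti,
    stats,
    grDevices,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
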