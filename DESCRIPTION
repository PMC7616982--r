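Package: skullpct
Title: Pseudo-CT Synthesis from MR and Transcranial Ultrasound Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates pseudo-CT head volumes from magnetic resonance images
    for transcranial ultrasound treatment planning, and evaluates them
    acoustically. Implements a classical linear mapping from zero-echo-time
    (ZTE) bone imaging to Hounsfield units, a small slice-stack U-Net
    regression trained on paired MR/CT data, conversion of CT-like volumes to
    acoustic medium property maps (density, sound speed, attenuation), a
    Rayleigh-integral and 2D Helmholtz continuous-wave field solver for an
    annular-array transducer, and image-space (MAE/RMSE) and focal
    (pressure, position, -6 dB volume) comparison metrics. A synthetic
    layered-skull head-phantom generator provides paired CT/ZTE/T1w volumes
    so the whole chain runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    EBImage,
    igraph,
    jsonlite,
    yaml,
    tibble,
    stats,
    utils,
    methods
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
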