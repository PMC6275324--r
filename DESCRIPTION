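Package: strokeshape
Title: Shape-Space Prediction of Ischemic Stroke Lesion Growth from CT Perfusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the follow-up ischemic stroke lesion from acute CT
    perfusion parameter maps (CBV and TTD). A 3D U-Net segments the ischemic
    core and the core+penumbra region, a convolutional auto-encoder embeds
    both segmentations in a learned low-dimensional shape space, and the
    follow-up lesion is predicted by time-normalized linear interpolation
    between the two latent codes with a monotone-growth constraint. All
    network layers (3D convolution, transposed convolution, batch
    normalization, pooling, trilinear resampling) and reverse-mode
    differentiation are implemented in the package on top of BLAS, so the
    full pipeline trains on CPU. A synthetic nested-shape lesion simulator
    generates CTP-like cases so every stage can be trained and evaluated
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
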