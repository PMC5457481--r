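Package: binodepth
Title: Binocular Depth Estimation by Detection and Proscription
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models of early binocular vision built around disparity-energy
    style simple units with Gabor receptive fields. Provides generators for
    correlated and anticorrelated random-dot stereograms, step-edge, wallpaper
    and half-occlusion (da Vinci) displays, and synthetic naturalistic stereo
    scenes; Shannon-information analysis of position, phase and hybrid
    disparity encoding; a small convolutional binocular neural network trained
    on near-versus-far depth discrimination; and a closed-form binocular
    likelihood model in which complex units read out simple-unit activity with
    weights equal to the interocular receptive-field cross-correlogram, so
    that dissimilar ("what not") features supply suppressive evidence against
    unlikely depth interpretations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    png
Config/testthat/edition: 3
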