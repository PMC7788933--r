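Package: pyconvunet
Title: Pyramidal-Convolution U-Net for Biomedical Image Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds, trains and evaluates encoder-decoder segmentation
    networks for single-channel biomedical images, with the standard U-Net as
    baseline and a lightweight variant whose 3x3 convolutions are replaced by
    multi-level pyramidal convolutions (parallel grouped convolutions of
    increasing kernel size and decreasing kernel depth, concatenated along
    channels).  Ships a closed-form parameter and multiply-accumulate
    accounting for both convolution families together with an enumeration
    oracle, mean-IoU and Dice evaluation from pooled confusion counts, the
    flip/rotation augmentation protocol with a seeded 80/20 split, and a
    seeded generator of synthetic CT-organ-like and
    electron-microscopy-membrane-like images so the whole pipeline is testable
    at desk scale without external data.  The convolutional engine (grouped
    and transposed convolutions, batch normalization, pooling, Adam) is
    implemented in compiled code via 'RcppArmadillo'.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    ggplot2,
    rlang,
    generics,
    png,
    tiff,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
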