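Package: pearnet
Title: Lightweight Single-Stage Pear Detection Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
                  email = "author@example.org")
Description: Implementation of a lightweight single-stage fruit detector for
    orchard picking robots: a reconstructed backbone built from channel-shuffle
    and inverted-shuffle blocks with convolutional block attention (CBAM),
    Hard-Swish activations, a scale-weighted confidence loss with CIoU box
    regression, and the matching evaluation protocol (NMS, precision/recall/F1,
    AP at IoU 0.5, stratified reporting by shade degree, background complexity
    and illumination). Includes architecture accounting (FLOPs by the
    convolution-layer product formula, half-precision serialized volume), a
    synthetic orchard-scene generator with exact occlusion ground truth, and a
    seeded training loop, so every component is exercisable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
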