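Package: lesionseg
Title: Attention Residual U-Net Segmentation of Gastrointestinal Lesion Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semantic segmentation of lesions (polyps, bleeding) in
    gastrointestinal endoscopy images with an attention residual U-Net:
    a U-Net encoder-decoder whose encoder uses residual convolution
    blocks and whose skip connections pass through additive attention
    gates. Provides paired image/mask input-output and preprocessing,
    paired geometric augmentation, a synthetic lesion-scene generator
    for download-free testing, the full network family (U-Net, attention
    U-Net, attention residual U-Net) with hand-derived backpropagation
    and Adam training with early stopping, pixelwise evaluation metrics
    (accuracy, Dice coefficient, Jaccard index), and a command-line
    interface. Convolution primitives are implemented in C++ via
    RcppArmadillo.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
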