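Package: desmokr
Title: Unpaired Desmoking of Laparoscopic Images with Chromatic and
    Dark-Channel Priors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Removes electrocautery smoke from laparoscopic video frames by
    unpaired image-to-image translation.  A cycle-consistent adversarial
    network (ResNet generators, PatchGAN discriminators, least-squares
    adversarial objective) is augmented with two smoke-aware losses: an
    inter-channel discrepancy term that detects the achromatic cast of
    dense smoke, and a dark-channel prior term that penalises residual
    haze.  The package also provides the dark channel and its soft-matting
    refinement, a scattering-model smoke simulator for generating unpaired
    clear/hazy fixtures, and referenceless image-quality metrics (a
    just-noticeable-blur sharpness metric, a visible-edge restoration
    rate, and a dark-channel fog-density proxy) for evaluating desmoked
    output without ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    Matrix,
    Rcpp,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
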