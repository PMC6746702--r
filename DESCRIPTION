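Package: octseg
Title: Chorio-Retinal Boundary Segmentation in OCT B-Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segmentation of the inner limiting membrane (ILM), the outer
    retinal pigment epithelium boundary (RPE) and the choroid-scleral
    interface (CSI) in optical coherence tomography (OCT) B-scans. Implements
    two supervised pipelines: patch-based pixel classification with small
    convolutional or recurrent networks, and semantic segmentation with
    U-Net encoder-decoder variants (residual blocks, recurrent bottleneck,
    squeeze-and-excitation blocks). Network boundary probability maps are
    delineated with a shortest-path graph search over column-monotone paths,
    and results are scored with post-segmentation Dice overlap and signed /
    absolute boundary position errors. Includes attenuation-compensation
    contrast enhancement, a synthetic layered-phantom B-scan generator with
    known ground truth, and a compact CPU training engine with hand-written
    backpropagation used by both pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    optparse
Config/testthat/edition: 3
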