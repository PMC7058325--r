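Package: retinavasc
Title: Retinal Microvascular Morphology Analysis with Vessel-Only CNN Classification and Grad-CAM Attribution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully reproducible pipeline for studying how
    hypertension-associated changes in retinal branching geometry can be
    detected from fundus photographs. Provides a synthetic vascular-tree
    cohort generator (Murray's-law bifurcation geometry with a controllable
    class-conditional branching effect), fundus-style image preprocessing
    (auto-crop, resize, CLAHE, gamma correction), a U-Net-derived vessel
    segmenter producing vessel-only images, a small convolutional network
    classifier with nested five-fold cross-validation, confusion-matrix and
    ROC evaluation, and Grad-CAM class-activation attribution with a
    bifurcation-enrichment statistic. The convolutional engine is
    implemented in-package on RcppArmadillo.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    Rcpp,
    jsonlite,
    yaml,
    png
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
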