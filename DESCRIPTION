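Package: carotidseg
Title: Cascaded Carotid Lumen Segmentation and NASCET Stenosis Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Three-stage pipeline for extracranial carotid artery analysis on
    high-resolution black-blood MRI volumes: slice-wise localization of the
    carotid region of interest with a 2D U-Net, volumetric lumen segmentation
    of the cropped region with a residual-encoder 3D U-Net, and geometric
    stenosis quantification by centerline extraction, vessel straightening,
    lumen-area profiling and the NASCET percent-diameter criterion. Includes a
    seeded synthetic bifurcating-vessel phantom generator with parametric focal
    stenoses for end-to-end testing, a compact self-contained U-Net training
    engine (SGD with Nesterov momentum, polynomial learning-rate decay, deep
    supervision, combined binary cross-entropy and Dice loss, five-fold
    cross-validation with fold ensembling), and evaluation statistics:
    overlap and surface-distance segmentation metrics, diagnostic accuracy
    metrics with AUC, Lin's concordance correlation, intraclass correlation,
    and the Wilcoxon signed-rank test.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
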