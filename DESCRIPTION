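Package: epiderm
Title: Quantification of UV-Induced Cell Damage in Stained Epidermis Histology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying DNA damage in immunohistochemically stained
    epidermis sections. Implements two per-sample damage scores, the
    nuclei ratio S_nuclei = N_dmg / N_all and the area ratio
    S_area = A_dmg / A_epi derived from a three-class segmentation
    (background, healthy epidermis, damaged epidermis); convolutional
    segmentation (U-Net family) and regression (VGG16-style backbone)
    estimators with their full training recipes, implemented on a compact
    CPU neural-network engine; stratified k-fold evaluation with MAE,
    macro-averaged IoU and pixel accuracy; a paired-bootstrap analysis of
    interobserver agreement; and a synthetic stained-epidermis generator
    with exact ground truth and a calibratable annotator-noise model, so
    the entire pipeline is testable without access to slide scans.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    png,
    EBImage,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
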