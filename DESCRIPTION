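Package: busseg
Title: Breast Ultrasound Mass Segmentation with a U-Net Ensemble and a
    Level-Set Baseline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated segmentation of suspicious breast masses in B-mode
    ultrasound images. Implements a ten-member U-net ensemble fused by
    per-pixel majority voting ("Multi U-net"), trained with a negative
    soft-Dice loss under patient-grouped ten-fold cross-validation, together
    with a seeded distance-regularized level-set (DRLSE) comparison
    algorithm and a Dice / true-positive-fraction / false-positive-fraction
    evaluation protocol with stratified summaries. A speckle-phantom
    simulator generates B-mode-like images with known lesion masks
    (hypoechoic core, irregular margins, posterior acoustic shadowing,
    hyperechoic halo) so the full pipeline runs without clinical data. The
    convolutional networks, their backpropagation and optimizers are
    implemented natively on BLAS matrix products.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    dplyr,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
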