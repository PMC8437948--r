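Package: psoriabench
Title: Psoriasis Lesion Segmentation, Patch Decomposition and Severity
    Classification Workbench
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end workbench for image-based assessment of
    psoriasis severity from local lesion photographs.  Provides a seeded
    synthetic lesion-scene generator with ground-truth masks, automatic
    lesion segmentation by SLIC superpixels with local k-means colour
    clustering in CIE-L*a*b* space, a reaction-diffusion level-set
    alternative, five-indicator segmentation similarity evaluation (Dice,
    global consistency error, variation of information, Hausdorff
    distance, Rand index), decomposition of segmented lesions into
    erythema and scale patch images, crop and affine data augmentation,
    texture/colour/spectrum feature extraction (co-occurrence, run-length,
    histogram, semi-variogram, local binary patterns, per-channel colour
    statistics, Gabor bank, Zernike moments), three-filter consensus
    feature selection (mRMR, chi-squared, ReliefF), six severity
    classifiers evaluated by repeated stratified cross-validation with
    seven agreement metrics, and PASI score aggregation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    class,
    dplyr,
    e1071,
    EBImage,
    farver,
    generics,
    ggplot2,
    jpeg,
    png,
    purrr,
    randomForest,
    Rcpp,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
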