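Package: phenocloud
Title: Weed Plant Phenotyping from Photogrammetric Point Clouds and Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-reconstruction phenotyping of single weed plants from
    structure-from-motion / multi-view-stereo outputs. Filters and
    scale-calibrates 3D point clouds, extracts plant height (cylindrical stem
    method) and leaf area (triangle-sum over the mesh), quantifies
    ground-truth leaf area from overhead images of detached leaves (linear
    RGB index, Otsu thresholding, reference-square scaling), and validates
    estimates against ground truth with correlation, regression, RMSE and
    percentage-error statistics. Ships a parametric synthetic-plant generator
    (dicot and monocot morphotypes with exactly known traits) so the whole
    pipeline can be exercised and benchmarked without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    png,
    pracma,
    withr,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    optparse
Config/testthat/edition: 3
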