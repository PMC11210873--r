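Package: kforest
Title: Distance-Varying Cell-Cell Interaction Discovery with K Functions and Random Forests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies cell-cell spatial interactions in multiplexed tissue
    images (e.g. MIBI) that predict a patient-level outcome. Per-image
    cross-type Ripley K functions with isotropic edge correction are averaged
    within patients, reduced to functional principal component scores, and fed
    with patient meta-variables into a Gini node-purity random forest.
    Permutation-based synthetic ("knock-off") variables calibrate variable
    importance and yield noise and interpolation significance thresholds that
    control the family-wise false discovery rate. Includes a nested
    modified-Thomas-process cohort simulator and the false-discovery-rate and
    power experiments used to validate the thresholds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    readr,
    stats,
    tibble,
    tidyr,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    rpart,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
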