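Package: felifat
Title: Postmortem Body-Fat Quantification in Cats from CT and Falciform Fat
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies feline total body fat from whole-body computed
    tomography by Hounsfield-unit histogram segmentation (fat/lean peak
    midpoint thresholding and a 350 HU bone rule), computes the body-fat
    percentage, body-fat volume, total body bone volume, and the
    size-normalized body-fat volume, and relates them to the falciform
    fat pad weight to femur length ratio (FFR) measured at necropsy.
    Derives overweight and obesity cutoffs from fat-category medians,
    chains them through regression to FFR and percent-body-fat scales,
    classifies cats by FFR, and evaluates diagnostic performance with
    exact binomial confidence intervals. Ships a synthetic CT phantom
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
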