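Package: brainquantile
Title: Scalar-on-Image Quantile Regression for Brain-Age Prediction Intervals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Normative brain-age modelling from registered 3D structural
    images with per-subject prediction intervals. Volumes are projected onto a
    tensor-product quadratic B-spline basis restricted to a smooth brain mask,
    reduced by functional principal component analysis in coefficient space,
    and chronological age is regressed on the component scores with
    LASSO-penalised linear quantile regression at several quantile levels.
    The package provides cross-validated normative training on controls,
    brain-predicted age difference (brainPAD), interval coverage diagnostics,
    voxelwise functional-coefficient maps, a synthetic cohort generator with
    known ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    splines,
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    withr,
    readr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
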