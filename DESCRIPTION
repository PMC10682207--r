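Package: canopylcc
Title: Canopy Hyperspectral Estimation of Leaf Chlorophyll Content
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-simulates forest canopy reflectance with a
    PROSPECT + SAILH + FLIM (INFORM-style) radiative-transfer chain,
    regenerates a full-factorial simulated jujube-canopy dataset, and
    estimates leaf chlorophyll content from original, first- and
    second-derivative spectra via LASSO / elastic-net band selection
    (cyclic coordinate descent with cross-validated regularization paths)
    followed by RBF-kernel support vector regression with cross-validated
    grid search.  Includes a synthetic field-campaign generator emulating
    a SPAD-characterised orchard survey, evaluation utilities
    (correlation-form R-squared, RMSE), plotting methods and a
    config-driven pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    e1071,
    signal,
    pracma,
    withr,
    yaml,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    optparse
Config/testthat/edition: 3
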