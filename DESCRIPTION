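Package: reefsdm
Title: Uncertainty-Aware Species Distribution Modelling for Benthic Habitats
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fits boosted regression tree (BRT) species distribution models for
    rare benthic assemblages on high-resolution raster grids, with
    cross-validated tree-count selection and hyperparameter tuning by percent
    deviance explained, bootstrap ensembles yielding per-cell mean probability
    and coefficient-of-variation (precision) surfaces, four ROC-based
    presence/absence threshold optimizers (sensitivity-equals-specificity,
    maximum sensitivity plus specificity, predicted-prevalence-equals-observed,
    maximum kappa), probability-by-precision tercile combination maps, and
    zonal area accounting against management-zone polygons. Includes a
    synthetic seascape simulator with a known true occurrence probability
    surface so the full workflow is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
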