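Package: foragehtp
Title: Simulation and Validation of UAV High-Throughput Phenotyping for
    Forage Dry Matter Yield
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, simulation-driven pipeline for validating
    image-based high-throughput phenotyping (HTP) of dry matter yield in
    forage breeding trials. Generates synthetic alpha-lattice trials with
    family, block and AR1xAR1 spatially correlated residual effects,
    renders per-plot canopy images and an orthomosaic, extracts plot
    patches, trains small convolutional regression networks with k-fold
    out-of-fold prediction to produce HTP traits, evaluates them (MAE,
    RMSE, Pearson r, histogram intersection), fits the REML/BLUP linear
    mixed model with separable AR1 residual correlation to estimate
    genetic variance and Cullis broad-sense heritability, and computes
    direct and correlated responses to selection under different
    selection intensities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    png,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    lme4,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
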