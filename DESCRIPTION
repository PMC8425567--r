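Package: mrfnowcast
Title: Multivariate Mahalanobis Random Forests for Poverty and Malnutrition Nowcasting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Joint prediction of correlated poverty and malnutrition prevalence
    rates at survey-cluster (enumeration-area) level from open geospatial
    covariates. Implements multivariate regression forests whose node splits
    minimise a Mahalanobis cost weighted by a feasible-GLS estimate of the
    residual precision matrix, mean-decrease-impurity importance, sequential
    nowcasting and contemporaneous cross-validation evaluation regimes with
    out-of-sample r-squared and normalised RMSE at three aggregation levels,
    the covariate-construction rules for seasonal remote-sensing anomalies,
    market food-price windows and conflict-event counts, and a synthetic-world
    generator emulating the enumeration-area data structure for end-to-end
    testing without any download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    generics,
    geosphere,
    ggplot2,
    purrr,
    Rcpp,
    readr,
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
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
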