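Package: spatzone
Title: Spatial Subsetting and Integrative Modeling of Multiplexed Tissue Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Zonal analysis of highly multiplexed tissue images such as imaging
    mass cytometry (IMC). Converts binary tumor masks into signed Euclidean
    border distances, assigns single cells to stroma / tumor-front / tumor-core
    zones, and builds zone-normalized feature classes (zonal densities,
    functional marker means, spatial metavariables, and neighborhood
    coefficients). Includes reproducibility analytics (intrapatient,
    interpatient and inter-cohort coefficients of variation and correlations),
    a stability-selection LASSO with late-fusion logistic classification of
    tumor grade evaluated by Monte Carlo cross-validation, and a seeded
    synthetic cohort generator that emulates the statistical structure of an
    IMC study for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    glmnet,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
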