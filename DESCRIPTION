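Package: fieldkrige
Title: Spatial Denoising of Field Trials via Kriged Soil-Property
    Principal Components
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies, estimates, and removes the effects of spatially
    distributed soil properties on field-trial phenotypes and microbiome
    count tables. Provides design-effect residualization for split-plot
    layouts, empirical semivariograms with six variogram families fitted
    by weighted least squares and selected by minimum sum-of-squared
    errors, ordinary kriging with leave-one-out cross-validation,
    likelihood-ratio tests for evidence of spatial structure, principal
    component regression with spatially correlated random effects
    (identity link for continuous traits, zero-inflated negative
    binomial for operational taxonomic unit counts), Canberra-distance
    constrained permutation ANOVA, hinge change-point screening of
    microbe-phenotype associations with false-discovery-rate control,
    and a synthetic split-plot field generator with known spatial
    structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    car,
    dplyr,
    generics,
    ggplot2,
    glmmTMB,
    jsonlite,
    nlme,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
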