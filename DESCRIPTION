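Package: richscape
Title: Landscape Metrics and Variation Partitioning for Urban Vertebrate
    Richness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how landscape structure versus the abiotic
    environment explains vertebrate species richness across groups of urban
    landscapes. Computes class-level landscape metrics (class area, edge
    length between class pairs, patch cohesion, edge density, largest patch
    index) from categorical land-use rasters, assembles per-landscape
    predictor tables with stepwise collinearity pruning, fits log-link
    Poisson regressions with exhaustive best-subset selection under an
    information criterion, partitions explained deviance into unique
    landscape, unique environmental, shared, and unexplained fractions via
    adjusted pseudo-R-squared, and compares fractions across groups with
    ANOVA and pairwise t-tests. A neutral-landscape synthetic data module
    (modified random clusters) generates land-use grids, correlated
    environmental covariates, and Poisson richness counts from known
    coefficients, so the whole pipeline is testable without GIS downloads.
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
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
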