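Package: poicrime
Title: Sparse Spatial Modelling of Urban Violent Crime from Point-of-Interest Densities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Models the spatial density of urban violent crime as a sparse
    linear combination of kernel-smoothed point-of-interest (POI) class
    densities. Provides readers for open police crime extracts and classed
    POI tables, six-kernel two-dimensional kernel density estimation over a
    regular study grid, L1-penalised (LASSO) selection of a fixed number of
    POI classes with a post-selection least-squares refit, an alcohol-outlet
    baseline, repeated split-half and leave-one-city-out cross-validation,
    kernel/bandwidth/penalty sweeps, and a synthetic-city generator that
    draws crime incidents from a known POI-weight superposition density and
    emulates the open-data anonymisation (snap-to-nearest-point) step.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    MASS,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    knitr,
    rmarkdown
Config/testthat/edition: 3
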