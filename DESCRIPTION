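Package: soil2leaf
Title: Soil-to-Plant Heavy-Metal Transfer Analysis for Orchard Monitoring
Version: 0.1.0
Authors@R:
    person("Orchard", "Analytics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing paired soil and leaf measurements from
    orchard monitoring surveys: chlorophyll quantification from methanol
    extract absorbances, bioaccumulation factor (BAF) indices, site-level
    descriptive and inferential statistics (Welch one-way ANOVA with
    Games-Howell post hoc comparisons, correlation matrices with strength
    categories), multivariate structure discovery (covariance PCA with
    varimax rotation, Ward hierarchical clustering, stepwise linear
    discriminant analysis), NIPALS partial least squares regression for
    predicting leaf traits from soil metals, and log-normal Monte Carlo
    simulation of exceedance risk against food-safety thresholds. Includes
    a synthetic orchard data generator emulating a 20-site by 4-tree
    survey design for end-to-end testing, and a scripted pipeline that
    runs every stage reproducibly from a single seed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
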