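Package: quadtrial
Title: Design, Simulation and Estimation for Quadruplet-Blocked Cluster
    Randomized Trials with Embedded Placebos
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A design-simulate-estimate pipeline for two-stage cluster
    randomized trials of the kind used to evaluate financial incentives for
    COVID-19 vaccination in rural Ghana. Implements population-ranked
    quadruplet blocking of village clusters, population-share weighted
    quadruplet sampling, within-quadruplet arm assignment, and 25% embedded
    placebo videos within treated villages; a synthetic-population generator
    with logistic-normal clustered binary outcomes calibrated to target
    intracluster correlations, covariate distributions, spillover effects and
    attrition; cluster-robust difference-in-means contrasts, ANOVA
    intracluster correlation estimates, cluster-robust logistic regression
    with sandwich covariance, spillover estimands from embedded placebos and
    untreated residents, covariate balance diagnostics, inverse probability
    weighting for attrition, leave-one-district-out sensitivity,
    randomization inference p-values, and simulation-based power analysis.
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
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    geosphere,
    withr,
    optparse
Config/testthat/edition: 3
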