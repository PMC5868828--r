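Package: carnipop
Title: Range-Wide Carnivore Population Estimation from Density and
    Occurrence Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating the total population of a wide-ranging
    carnivore from heterogeneous camera-trap density estimates and
    presence/absence records. Implements rescaling of non-spatial (half
    mean-maximum-distance-moved buffer) density estimates to the spatially
    explicit capture-recapture level via paired regression, all-subsets
    multiple linear and logistic regression with Bayesian Information
    Criterion selection, semi-partial correlations, bootstrap coefficient
    bias, spatial thinning and pseudo-absence generation, and a
    hierarchical Bernoulli-by-Normal model that combines density and
    occurrence predictions over a grid by Markov chain Monte Carlo to give
    per-cell and total abundance with credible intervals. A synthetic
    landscape generator and a replicated simulation-validation driver
    support testing of the whole pipeline without proprietary rasters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    geosphere
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
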