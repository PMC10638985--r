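Package: mdcfa
Title: Modeling Missing Data in Factor Analysis of Binary Items
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Confirmatory factor analysis of tetrachoric correlation
    matrices with an additional missing data latent variable that accounts
    for the systematic variation produced by planned missing data designs.
    Includes generation of unidimensional binary data with planned
    missingness, two-step maximum likelihood tetrachoric estimation with a
    zero-replacement policy and ridge smoothing, one-factor and
    bifactor-type missing-data models with fixed or free loadings,
    Satorra-Bentler scaled test statistics with bootstrap estimation of
    the asymptotic covariance of the correlations, standard fit indices
    (RMSEA, SRMR, NNFI, CFI, AIC), and a simulation harness with
    table-style summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mvtnorm,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
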