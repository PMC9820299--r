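Package: wqsource
Title: Water Quality Index Modelling and Pollution Source Apportionment
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end surface-water quality analysis: additive water quality
    index (WQI) scoring with configurable sub-index curves and weights,
    regression-forest modelling of WQI with mean-decrease-impurity feature
    importance for minimal-parameter (WQI_RFmin) selection,
    uncertainty-weighted positive matrix factorization (PMF) for pollution
    source apportionment, and a combination statistic attributing WQI
    variation to the identified sources. Includes a synthetic monitoring-data
    generator with planted source structure for validation with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
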