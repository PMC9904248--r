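Package: surveyfuse
Title: Data Integration for Non-Probability Health Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Corrects selection bias in convenience (non-probability) health
    surveys by integrating them with probability-sample reference surveys.
    Implements composite weighting for stacked survey waves, calibration
    weighting of the non-probability sample to benchmark totals (closed-form
    quadratic-distance calibration and raking by iterative proportional
    fitting), sequential mass imputation of outcome variables by fully
    conditional specification, design-weighted descriptive estimation with
    first-order Rao-Scott chi-square tests, and a synthetic finite-population
    harness that measures each estimator's bias against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
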