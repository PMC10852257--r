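Package: agrorules
Title: Association Rule Mining Between Monthly Climate and Crop Yield
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines association rules linking discretized monthly climate
    variables (temperature, humidity, rainfall, sunshine, evapotranspiration)
    to crop yield categories within agro-ecological zones. Provides a
    from-scratch FP-Growth frequent-itemset miner with an Apriori oracle,
    mean +/- standard-deviation three-level discretization, a correlation
    filter for redundant predictors, a zone-structured synthetic
    climate-yield generator with plantable association rules, and a
    reproducible end-to-end pipeline with support/confidence/lift scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
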