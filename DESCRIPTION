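Package: vitalgreen
Title: Linking Landbird Vital Rates to Rainfall and Vegetation Greenness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relating remote-sensed vegetation greenness (EVI) and
    rainfall to landbird demographic rates estimated from constant-effort
    mist-netting data. Builds seasonal greenness covariates from monthly
    station-scale EVI, fits a binomial logit-linear productivity index from
    age-ratio capture data, and estimates adult apparent survival with a
    constrained Barker joint live-recapture/between-period-detection
    likelihood, comparing covariate structures by AICc and Akaike weights.
    Includes a synthetic-data generator that reproduces the statistical
    structure of all four input streams (rainfall, EVI, captures, effort) so
    the full inference chain is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
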