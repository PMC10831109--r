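Package: plantshift
Title: Diet Replacement Scenarios for Nutrition, Environment and Cost
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Models national diet-shift scenarios in which animal-source
    foods are replaced by plant-based alternatives or whole plant foods,
    under mass- or energy-based functional units. Scores each scenario
    against daily nutrient recommendations, computes greenhouse gas,
    cropland and freshwater footprints with food-group contributions, and
    accounts for daily food expenditure, with quantile-based uncertainty
    sweeps and within-group "conscious consumer" bounds. Ships a
    seed-reproducible synthetic food-database generator so the full
    pipeline runs without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
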