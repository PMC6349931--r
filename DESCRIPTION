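Package: aridcast
Title: Forecasting Dryland Vegetation Condition from Assimilated Water Storage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for forecasting dryland vegetation greenness anomalies from
    the water stored at and below the land surface. Implements a layered
    soil-water bucket model, assimilation of contrasting satellite-like water
    observations (daily near-surface soil moisture, monthly total-column
    storage, 8-day surface-water fraction) with an ensemble Kalman smoother
    over fixed one-month windows, inference of the vegetation-accessible
    storage depth via lagged Spearman rank correlation, and statistical
    greenness forecasts with persistence, climatology and antecedent
    precipitation index baselines evaluated by segment-wise hindcast
    cross-validation. Includes a synthetic-data generator so the whole chain
    is testable without satellite downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
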