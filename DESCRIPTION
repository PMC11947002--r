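Package: casetemps
Title: Case Time-Series Distributed Lag Non-Linear Models for
    Temperature and Health
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Small-area case time-series analysis of short-term
    temperature-health associations with distributed lag non-linear
    models (DLNMs). Builds temperature-by-lag cross-bases from natural
    cubic splines, fits conditional quasi-Poisson regressions with
    fine-scale zone-by-year-by-month strata absorbed, extracts
    cumulative exposure-response curves with relative risks at
    temperature percentiles and the minimum-risk temperature, pools
    region-specific coefficient vectors by multivariate inverse-variance
    meta-analysis, and stratifies analyses by diagnosis, demographic and
    community segregation (Index of Concentration at the Extremes)
    subgroups. Includes a synthetic zone-day panel generator with known
    injected exposure-lag-response surfaces for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    splines,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
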