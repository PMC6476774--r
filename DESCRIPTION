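Package: gencycles
Title: Generation-Cycle Analysis of Age-Structured Insect Population Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting and characterising generation cycles in weekly
    census time series from replicated insect mesocosm experiments. Provides
    periodogram estimation on square-root transformed counts with Monte-Carlo
    significance thresholds drawn from a negative-binomial white-noise null,
    loess detrending and Morlet continuous wavelet analysis with white-noise
    significance contours and a cone of influence, exact r x c contingency
    tests by full enumeration, factorial linear models with backward
    simplification, and a stage-structured stochastic simulator of stored
    product moth populations with asymmetric larval competition and
    cannibalism that generates census data with the structure the analysis
    assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    withr
Config/testthat/edition: 3
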