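Package: gappypollen
Title: Gappy-SVD Imputation and Simulation Studies for Daily Pollen Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Imputation of missing values in daily airborne pollen
    concentration series by iterative rank-truncated singular value
    decomposition (Gappy SVD) and by moving-mean interpolation, together
    with the machinery for a full simulation study: pollen-season
    definition by the 95-percentage cumulative method, a day-to-day
    Variation Index, controlled gap generation at fixed proportions and
    run lengths, RMSE evaluation, log-RMSE regression with
    heteroskedasticity-consistent standard errors, and a multi-year
    synthetic pollen generator so the whole study runs without any
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    sandwich,
    lmtest
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
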