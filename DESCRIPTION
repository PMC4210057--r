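Package: adstar
Title: Spatiotemporal Poisson Regression for Dust-Storm Exposure and Clinic Visits
Version: 0.1.0
Authors@R: person("adstar", "developers", role = c("aut", "cre"),
    email = "adstar@example.org")
Description: Structured additive regression (STAR) for daily district-level
    count data with environmental exposures. Fits Poisson models combining
    day-of-week and dust-storm-episode fixed effects, linear pollutant terms,
    P-spline smoothers with second-order random-walk penalties for calendar
    time and temperature, an intrinsic conditional-autoregressive (CAR)
    district effect, and a log-population offset. Smoothing variances are
    estimated by restricted maximum likelihood via Fellner-Schall updates
    (empirical Bayes). Includes AIC-based pollutant-subset selection,
    relative-rate effect reporting, a synthetic panel generator with known
    truth, and a reproducible simulate/fit/select/report pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    splines,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
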