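Package: streamfill
Title: Hybrid GAM-ARIMA Reconstruction of Missing High-Frequency
    Water-Quality Sensor Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconstructs missing observations in regular-grid,
    high-frequency in-situ water-quality time series (15-minute nitrate
    concentrations with co-located temperature, conductance, dissolved
    oxygen, turbidity and water-elevation sensors).  Each missing
    timestamp is predicted either by a penalized-spline generalized
    additive model selected by forward/backward stepwise AIC (when all
    required covariates are present) or by an AIC-selected ARIMA model
    fit to the preceding window of the series (when they are not), with
    95 percent prediction intervals in both cases.  Includes the
    missingness-simulation machinery (random point removal and
    contiguous day/week block removal), sensor-precision-based
    evaluation metrics (RMSE, PWPI, R-squared), and a synthetic
    river-chemistry generator with known ground truth for validating
    the whole pipeline without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    mgcv,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
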