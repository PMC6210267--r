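Package: priflux
Title: Cross-Calibrated PRI Sensor Time Series as Proxies of Canopy Light Use Efficiency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns paired narrowband (532/570 nm) radiometer signals into
    calibrated photochemical reflectance index (PRI) time series and validates
    them as proxies of canopy light use efficiency (LUE) against eddy-covariance
    derived gross primary productivity (GPP) and apparent quantum yield.
    Implements the offline diurnal white-panel cross-calibration procedure
    (per-waveband calibration functions of percent illumination within 3 degree
    solar-elevation bins), NOAA-form solar geometry, Ryan-Stolzenbach clear-sky
    irradiance, broadband NDVI and fAPAR canopy phenology tracking with
    second-derivative transition detection, u*-filtered flux partitioning with a
    rectangular-hyperbola light-response fit (Gauss-Newton), sPRI- and
    quantum-yield-driven LUE models of GPP, and a seeded synthetic-data
    generator with known ground truth for every estimated quantity.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    minpack.lm,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
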