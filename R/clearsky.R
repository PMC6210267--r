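#' Ryan-Stolzenbach clear-sky global radiation
#'
#' Models the clear-sky global (shortwave) radiation on a horizontal surface,
#'
#'   I = I0 * E * atc^m * sin(el)
#'
#' with `I0` = 1367 W m-2 the solar constant, `E` the Earth-Sun eccentricity
#' factor `1 + 0.033 cos(2 pi doy / 365)`, `atc` the atmospheric transmission
#' coefficient (valid range 0.70-0.91), and `m` the altitude-corrected
#' relative optical air mass
#'
#'   m = ((288 - 0.0065 z) / 288)^5.256 / (sin(el) + 0.15 (el + 3.885)^-1.253)
#'
#' where `el` is solar elevation in degrees and `z` the site altitude in m.
#' Radiation is 0 whenever the sun is at or below the horizon.
#'
#' @param site A [site_config()]; supplies `altitude_m` and `atc`.
#' @param elevation_deg Solar elevation, degrees (vectorised).
#' @param doy Day of year used for the Earth-Sun distance factor; default 81
#'   (an equinox, eccentricity factor near 1). Pass the actual day when
#'   modelling a dated series.
#'
#' @return Modeled clear-sky global radiation, W m-2.
#' @examples
#' site <- aspen_site()
#' modeled_clear_sky(site, c(10, 30, 50))
#' @export
modeled_clear_sky <- function(site, elevation_deg, doy = 81) {
  stopifnot(inherits(site, "site_config"))
  if (site$atc < 0.70 || site$atc > 0.91) {
    stop("`atc` outside the model's valid range [0.70, 0.91]", call. = FALSE)
  }
  i0 <- 1367 * (1 + 0.033 * cos(2 * pi * doy / 365))
  sinel <- sin(elevation_deg * pi / 180)
  press <- ((288 - 0.0065 * site$altitude_m) / 288)^5.256
  m <- press / (sinel + 0.15 * (elevation_deg + 3.885)^-1.253)
  out <- i0 * site$atc^m * sinel
  out[is.na(elevation_deg)] <- NA_real_
  out[!is.na(elevation_deg) & elevation_deg <= 0] <- 0
  out
}

#' Percent illumination from measured vs modeled radiation
#'
#' Percent illumination is the ratio of measured to modeled clear-sky global
#' radiation, times 100. It is the predictor of the cross-calibration
#' functions. When the modeled radiation falls below `floor_Wm2` (sun at or
#' near the horizon) the ratio is unstable and the value is returned as
#' missing rather than allowed to blow up. Values above 100% (cloud-edge
#' enhancement) are retained; [correction_ratio()] caps lookups at 120% so
#' calibration functions are never extrapolated far beyond their fitted
#' range.
#'
#' @param measured_Wm2 Measured global radiation, W m-2.
#' @param modeled_Wm2 Modeled clear-sky radiation, W m-2 (>= 0).
#' @param floor_Wm2 Modeled-radiation floor below which the ratio is flagged
#'   missing.
#'
#' @return Percent illumination (>= 0, possibly > 100), `NA` below the floor.
#' @examples
#' percent_illumination(c(800, 400, 100), c(800, 800, 0))
#' @export
percent_illumination <- function(measured_Wm2, modeled_Wm2, floor_Wm2 = 10) {
  stopifnot(all(modeled_Wm2 >= 0, na.rm = TRUE))
  out <- 100 * measured_Wm2 / modeled_Wm2
  out[is.na(modeled_Wm2) | modeled_Wm2 < floor_Wm2] <- NA_real_
  pmax(out, 0)
}
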