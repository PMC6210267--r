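#' Solar position (NOAA solar-calculator algorithm)
#'
#' Computes solar declination, elevation, azimuth and that civil day's
#' solar-noon elevation for each timestamp, using the equations behind
#' NOAA's solar position calculator (Meeus-style geometric mean longitude
#' and anomaly, equation of center, apparent longitude with the nutation
#' correction, corrected obliquity, then equation of time, hour angle and
#' spherical trigonometry). Accuracy is a few hundredths of a degree --
#' ample for assigning observations to 3 degree elevation bins. No
#' atmospheric refraction correction is applied; refraction only matters
#' below ~1 degree elevation, which falls in near-night bins excluded from
#' calibration fitting.
#'
#' @param site A [site_config()].
#' @param timestamp A `POSIXct` vector with a known timezone (converted to
#'   UTC internally). Timestamps without timezone information are rejected.
#'
#' @return A tibble with columns `timestamp` (UTC), `elevation_deg`,
#'   `azimuth_deg` (clockwise from north), `declination_deg` and
#'   `noon_elevation_deg` (the day's solar-noon elevation).
#' @examples
#' site <- aspen_site()
#' solar_position(site, as.POSIXct("2015-06-21 20:00", tz = "UTC"))
#' @export
solar_position <- function(site, timestamp) {
  stopifnot(inherits(site, "site_config"))
  if (!inherits(timestamp, "POSIXct")) {
    stop("`timestamp` must be POSIXct with an unambiguous UTC offset",
         call. = FALSE)
  }
  ts_utc <- lubridate::with_tz(timestamp, "UTC")

  pos <- noaa_solar(site$latitude_deg, site$longitude_deg, ts_utc)

  # solar noon of each civil UTC day: hour angle = 0 when
  # minutes_utc = 720 - 4*lon - eqtime
  day0 <- lubridate::floor_date(ts_utc, "day")
  noon_guess <- day0 + lubridate::dminutes(720 - 4 * site$longitude_deg)
  # one refinement: recompute the equation of time at the guessed noon
  eq1 <- noaa_solar(site$latitude_deg, site$longitude_deg, noon_guess)$eqtime_min
  noon <- day0 + lubridate::dminutes(720 - 4 * site$longitude_deg - eq1)
  noon_el <- noaa_solar(site$latitude_deg, site$longitude_deg, noon)$elevation_deg

  tibble::tibble(
    timestamp = ts_utc,
    elevation_deg = pos$elevation_deg,
    azimuth_deg = pos$azimuth_deg,
    declination_deg = pos$declination_deg,
    noon_elevation_deg = noon_el
  )
}

# NOAA solar-calculator position equations, vectorised over UTC POSIXct.
noaa_solar <- function(lat_deg, lon_deg, ts_utc) {
  deg2rad <- pi / 180
  hour_frac <- lubridate::hour(ts_utc) + lubridate::minute(ts_utc) / 60 +
    lubridate::second(ts_utc) / 3600

  jd <- as.numeric(ts_utc) / 86400 + 2440587.5
  jc <- (jd - 2451545) / 36525 # Julian centuries from J2000

  l0 <- (280.46646 + jc * (36000.76983 + 0.0003032 * jc)) %% 360
  m <- (357.52911 + jc * (35999.05029 - 0.0001537 * jc)) * deg2rad
  ecc <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)
  eq_center <- sin(m) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
    sin(2 * m) * (0.019993 - 0.000101 * jc) + sin(3 * m) * 0.000289
  true_long <- l0 + eq_center
  omega <- (125.04 - 1934.136 * jc) * deg2rad
  app_long <- (true_long - 0.00569 - 0.00478 * sin(omega)) * deg2rad

  mean_obliq <- 23 + (26 + (21.448 - jc * (46.815 + jc *
    (0.00059 - jc * 0.001813))) / 60) / 60
  obliq <- (mean_obliq + 0.00256 * cos(omega)) * deg2rad

  decl <- asin(sin(obliq) * sin(app_long))

  var_y <- tan(obliq / 2)^2
  l0r <- l0 * deg2rad
  eqtime <- 4 / deg2rad * (var_y * sin(2 * l0r) - 2 * ecc * sin(m) +
    4 * ecc * var_y * sin(m) * cos(2 * l0r) -
    0.5 * var_y^2 * sin(4 * l0r) - 1.25 * ecc^2 * sin(2 * m)) # minutes

  time_offset <- eqtime + 4 * lon_deg # minutes (UTC reference)
  tst <- hour_frac * 60 + time_offset # true solar time, minutes
  ha <- (tst / 4 - 180) * deg2rad # hour angle, rad

  lat <- lat_deg * deg2rad
  cos_zen <- sin(lat) * sin(decl) + cos(lat) * cos(decl) * cos(ha)
  cos_zen <- pmin(1, pmax(-1, cos_zen))
  zen <- acos(cos_zen)

  # azimuth clockwise from north via atan2 (stable at the poles of the
  # elevation formula)
  az <- atan2(
    -sin(ha) * cos(decl),
    cos(lat) * sin(decl) - sin(lat) * cos(decl) * cos(ha)
  ) / deg2rad
  az <- (az + 360) %% 360

  list(
    elevation_deg = 90 - zen / deg2rad,
    azimuth_deg = az,
    declination_deg = decl / deg2rad,
    eqtime_min = eqtime
  )
}

#' Solar-elevation bin index
#'
#' Assigns elevations to half-open bins `[lower, lower + width)` labelled by
#' `floor(elevation / width)`, the scheme the cross-calibration functions are
#' fitted within. The default 3 degree width corresponds to roughly 30 min of
#' solar motion at morning/evening, when elevation changes fastest. All
#' negative (night) elevations collapse to the sentinel bin `-1`.
#'
#' @param elevation_deg Numeric vector of solar elevations, degrees.
#' @param bin_width_deg Bin width, degrees (> 0).
#'
#' @return Integer vector of bin indices; a bin's lower edge in degrees is
#'   `index * bin_width_deg`. Night (elevation < 0) maps to `-1L`; `NA`
#'   stays `NA`.
#' @examples
#' elevation_bin(c(4.5, 41.9, -5))
#' @export
elevation_bin <- function(elevation_deg, bin_width_deg = 3) {
  stopifnot(bin_width_deg > 0)
  idx <- as.integer(floor(elevation_deg / bin_width_deg))
  idx[!is.na(elevation_deg) & elevation_deg < 0] <- -1L
  idx
}
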