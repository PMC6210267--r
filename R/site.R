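#' Site configuration
#'
#' Bundles the site coordinates and the pipeline thresholds that depend on
#' them. Longitude follows the east-positive convention, so a site in western
#' Canada has a negative longitude. The atmospheric transmission coefficient
#' `atc` parameterises the Ryan-Stolzenbach clear-sky model and must lie in
#' its documented valid range 0.70-0.91.
#'
#' @param latitude_deg Latitude in decimal degrees, north positive.
#' @param longitude_deg Longitude in decimal degrees, east positive.
#' @param altitude_m Site altitude above sea level, m.
#' @param utc_offset_h Offset of local standard time from UTC, hours.
#'   Used only when interpreting local-time inputs; all internal timestamps
#'   are UTC.
#' @param elevation_bin_width_deg Width of the solar-elevation bins used by
#'   the cross-calibration, degrees.
#' @param ustar_threshold_ms Friction-velocity threshold below which
#'   nighttime fluxes are discarded, m s-1.
#' @param atc Atmospheric transmission coefficient of the clear-sky model.
#'
#' @return An object of class `site_config` (a named list).
#' @examples
#' aspen_site()
#' @export
site_config <- function(latitude_deg,
                        longitude_deg,
                        altitude_m = 0,
                        utc_offset_h = 0,
                        elevation_bin_width_deg = 3,
                        ustar_threshold_ms = 0.21,
                        atc = 0.8) {
  stopifnot(
    is.numeric(latitude_deg), length(latitude_deg) == 1,
    abs(latitude_deg) <= 90,
    is.numeric(longitude_deg), length(longitude_deg) == 1,
    abs(longitude_deg) <= 180,
    elevation_bin_width_deg > 0
  )
  if (atc < 0.70 || atc > 0.91) {
    stop("`atc` must lie in the Ryan-Stolzenbach valid range [0.70, 0.91]",
         call. = FALSE)
  }
  structure(
    list(
      latitude_deg = latitude_deg,
      longitude_deg = longitude_deg,
      altitude_m = altitude_m,
      utc_offset_h = utc_offset_h,
      elevation_bin_width_deg = elevation_bin_width_deg,
      ustar_threshold_ms = ustar_threshold_ms,
      atc = atc
    ),
    class = "site_config"
  )
}

#' @export
print.site_config <- function(x, ...) {
  cat(sprintf(
    "<site_config> lat %.4f, lon %.4f, alt %.0f m, UTC%+g; bins %g deg, u* %.2f m/s, atc %.2f\n",
    x$latitude_deg, x$longitude_deg, x$altitude_m, x$utc_offset_h,
    x$elevation_bin_width_deg, x$ustar_threshold_ms, x$atc
  ))
  invisible(x)
}

#' Default boreal aspen study site
#'
#' A boreal trembling-aspen stand in northwestern Alberta
#' (56.7439 N, 118.3439 W, 867 m a.s.l., UTC-7 standard time), the site
#' geometry the synthetic-data generator emulates.
#'
#' @return A [site_config()] object.
#' @export
aspen_site <- function() {
  site_config(
    latitude_deg = 56.7439,
    longitude_deg = -118.3439,
    altitude_m = 867,
    utc_offset_h = -7
  )
}
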