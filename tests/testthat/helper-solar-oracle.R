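# Independent solar-elevation oracle: Michalsky (1988) Astronomical-Almanac
# algorithm (ecliptic longitude -> right ascension / GMST -> hour angle),
# formulated completely differently from the fractional-year Fourier series
# used by the package. Quoted accuracy ~0.01 deg for 1950-2050; no
# refraction term, matching the implementation under test.
oracle_solar_elevation <- function(lat_deg, lon_deg, ts_utc) {
  rad <- pi / 180
  jd <- as.numeric(ts_utc) / 86400 + 2440587.5
  delta <- jd - 2451545.0
  hour_ut <- (jd + 0.5 - floor(jd + 0.5)) * 24

  mnlong <- (280.460 + 0.9856474 * delta) %% 360
  mnanom <- ((357.528 + 0.9856003 * delta) %% 360) * rad
  eclong <- ((mnlong + 1.915 * sin(mnanom) + 0.020 * sin(2 * mnanom)) %% 360) * rad
  oblqec <- (23.439 - 0.0000004 * delta) * rad

  ra <- atan2(cos(oblqec) * sin(eclong), cos(eclong))
  ra <- ra %% (2 * pi)
  dec <- asin(sin(oblqec) * sin(eclong))

  gmst <- (6.697375 + 0.0657098242 * delta + hour_ut) %% 24
  lmst <- ((gmst + lon_deg / 15) %% 24) * 15 * rad
  ha <- lmst - ra
  ha <- ((ha + pi) %% (2 * pi)) - pi

  lat <- lat_deg * rad
  el <- asin(sin(dec) * sin(lat) + cos(dec) * cos(lat) * cos(ha))
  el / rad
}
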