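#' Configuration for the synthetic-data generator
#'
#' Collects every parameter of the simulated measurement system: site and
#' date ranges, the stochastic-cloudiness model, the fore-optic gain model
#' that the cross-calibration is meant to correct, canopy phenology, the
#' true LUE/PRI coupling, and the flux truth. Identical `seed` + config
#' yields bit-identical output.
#'
#' The fore-optic bias is multiplicative and linear in percent illumination
#' within each solar elevation:
#' `cc(band, illum, el) = base_band * 0.99 / pi * (1 + s_band * w(el) * (100 - illum) / 100)`
#' with elevation weight `w(el) = max(0.15, 1 - el / 60)` -- steeper
#' illumination sensitivity at low sun, near-flat functions at high sun,
#' and ratios scattering around the Lambertian value 0.99/pi. Because the
#' bias is linear in illumination per elevation, the binned linear
#' calibration functions are well-specified.
#'
#' @param seed Integer seed for all randomness.
#' @param site A [site_config()].
#' @param campaign_start,campaign_days White-panel campaign start date and
#'   length (default 23 days around the solstice, spanning elevations
#'   0-56 degrees).
#' @param season_start,season_end Canopy/flux season date range.
#' @param cloud_mu,cloud_phi,cloud_sd AR(1) cloudiness parameters in logit
#'   space at 1-min resolution (`cloud_phi` is the per-minute persistence);
#'   illumination fraction is `0.10 + 0.92 * plogis(z)`, allowing both deep
#'   overcast (< 15%) and cloud-edge enhancement (> 100%).
#' @param gain_base,gain_islope Named per-band (`"532"`, `"570"`) base gain
#'   and illumination sensitivity of the fore-optic bias model.
#' @param ratio_noise_sd White-panel ratio noise at high sun; the actual
#'   noise is `ratio_noise_sd * (1 + 2 * w(el))`, emulating the larger
#'   specular scatter at low elevations.
#' @param rad_noise_sd Relative noise of the canopy radiance channels.
#' @param ndvi_base,ndvi_peak,spring_midpoint_doy,spring_rate,fall_rate,
#'   senescence_inflection_doy Double-logistic NDVI phenology; the
#'   inflection day is where the NDVI second derivative is most negative.
#' @param amax_peak,alpha_peak,r10,q10 Flux truth: peak light-response
#'   parameters (scaled down through senescence with canopy phenology) and
#'   respiration parameters.
#' @param alpha_day_sd,alpha_day_phi Day-to-day variability of the true
#'   apparent quantum yield: a multiplicative lognormal AR(1) factor
#'   (`sd` in log space, daily persistence `phi`) emulating the
#'   meteorological (temperature/VPD/stress) modulation of quantum yield
#'   around its phenological trajectory.
#' @param nee_noise_sd NEE measurement noise, micro-mol m-2 s-1.
#' @param spri0,spri_lue_slope sPRI-LUE coupling: true
#'   `sPRI = spri0 + spri_lue_slope * LUE` during maturity. The scale is
#'   set so the seasonal sPRI standard deviation and its efficiency
#'   correlations land in the range canopy PRI studies report (sigma of
#'   order 0.1, r2 of order 0.5-0.6), rather than an implausibly clean
#'   proxy.
#' @param spri_noise_sd Canopy-scale sPRI nuisance scatter (sunfleck/
#'   shadow-fraction and background variation): 30-min persistent AR(1),
#'   stationary sd `spri_noise_sd * (0.6 + 0.4 * phen)` so variability
#'   shrinks as the canopy thins.
#' @param spri_sen_drift Constitutive senescence drift coefficient: during
#'   senescence true sPRI gains `spri_sen_drift * (fAPAR - fAPAR_transition)`
#'   plus extra noise `spri_sen_noise_sd`, encoding the structural
#'   (pigment-pool/canopy) influence on the PRI signal.
#' @param spri_sen_noise_sd Extra sPRI truth noise during senescence.
#' @param rho570 Reference-band (570 nm) true reflectance factor.
#' @param az_amp Named per-band amplitude of the directional-reflectance
#'   (BRDF) artifact of the canopy deployment: measured radiance is
#'   modulated by `1 + az_amp_band * sin(azimuth - 180 deg)`. The
#'   cross-calibration does not model solar azimuth, so this artifact is
#'   deliberately uncorrectable -- it emulates the residual
#'   sun-canopy-sensor geometry error of corrected field PRI. Absent over
#'   the flat white panel (no BRDF), so the calibration campaign is clean.
#' @param precip_events_per_day Poisson rate of precipitation events.
#' @param par_fraction,par_umol_per_j PAR fraction of global shortwave and
#'   its quantum conversion (PPFD = global * 0.45 * 4.6).
#'
#' @return A `generator_config` list.
#' @export
generator_config <- function(seed = 1,
                             site = aspen_site(),
                             campaign_start = as.Date("2015-06-10"),
                             campaign_days = 23,
                             season_start = as.Date("2015-05-01"),
                             season_end = as.Date("2015-10-15"),
                             cloud_mu = 0.5,
                             cloud_phi = 0.999,
                             cloud_sd = 0.10,
                             gain_base = c("532" = 1.05, "570" = 0.95),
                             gain_islope = c("532" = 0.30, "570" = 0.22),
                             ratio_noise_sd = 0.002,
                             rad_noise_sd = 0.01,
                             ndvi_base = 0.30,
                             ndvi_peak = 0.78,
                             spring_midpoint_doy = 145,
                             spring_rate = 0.15,
                             fall_rate = 0.25,
                             senescence_inflection_doy = 233,
                             amax_peak = 25,
                             alpha_peak = 0.025,
                             alpha_day_sd = 0.15,
                             alpha_day_phi = 0.7,
                             r10 = 2,
                             q10 = 2,
                             nee_noise_sd = 1.0,
                             spri0 = 0.30,
                             spri_lue_slope = 12,
                             spri_noise_sd = 0.06,
                             spri_sen_drift = 0.35,
                             spri_sen_noise_sd = 0.07,
                             rho570 = 0.055,
                             az_amp = c("532" = 0.015, "570" = -0.015),
                             precip_events_per_day = 0.15,
                             par_fraction = 0.45,
                             par_umol_per_j = 4.6) {
  stopifnot(inherits(site, "site_config"), ratio_noise_sd >= 0,
            rad_noise_sd >= 0, nee_noise_sd >= 0, spri_sen_noise_sd >= 0)
  structure(as.list(environment()), class = "generator_config")
}

# elevation weight of the fore-optic illumination sensitivity; floored at
# 0.15 because some diffuse-fraction sensitivity remains even at high sun
gain_elevation_weight <- function(elevation_deg) {
  pmax(0.15, 1 - elevation_deg / 60)
}

# true cross-calibration ratio of the simulated sensor pair
true_cc_ratio <- function(config, band, illumination_pct, elevation_deg) {
  b <- as.character(band)
  base <- config$gain_base[b] * 0.99 / pi
  s <- config$gain_islope[b]
  w <- gain_elevation_weight(elevation_deg)
  unname(base * (1 + s * w * (100 - illumination_pct) / 100))
}

#' Analytic calibration-function truth per elevation bin
#'
#' The generator's fore-optic bias is linear in illumination at fixed
#' elevation, so the true calibration function of a bin (evaluated at the
#' bin's centre elevation) has closed-form slope and intercept. Used to
#' score parameter recovery of [fit_calibration()].
#'
#' @param config A [generator_config()].
#' @param bins Integer bin indices (lower edge = `bin * bin_width`).
#' @param el_deg Elevation at which to evaluate each bin's truth; defaults
#'   to the bin centre. Pass the mean observed elevation per bin when
#'   scoring a fit against a campaign whose visits are not uniform within
#'   the bin (e.g. a bin truncated by the site's maximum solar elevation).
#'
#' @return A tibble with `band`, `bin`, `slope`, `intercept`.
#' @export
true_calibration <- function(config, bins, el_deg = NULL) {
  bw <- config$site$elevation_bin_width_deg
  if (is.null(el_deg)) el_deg <- (as.integer(bins) + 0.5) * bw
  stopifnot(length(el_deg) == length(bins))
  tidyr::expand_grid(band = c(532, 570),
                     tibble::tibble(bin = as.integer(bins),
                                    el_mid = el_deg)) |>
    dplyr::mutate(
      base = config$gain_base[as.character(.data$band)] * 0.99 / pi,
      s = config$gain_islope[as.character(.data$band)],
      w = gain_elevation_weight(.data$el_mid),
      slope = unname(-.data$base * .data$s * .data$w / 100),
      intercept = unname(.data$base * (1 + .data$s * .data$w))
    ) |>
    dplyr::select("band", "bin", "slope", "intercept")
}

# logit-space AR(1) cloudiness -> illumination fraction
simulate_illumination <- function(config, n, step_min) {
  phi <- config$cloud_phi^step_min
  sd_step <- config$cloud_sd * sqrt(sum(config$cloud_phi^(2 * (seq_len(step_min) - 1))))
  z <- numeric(n)
  sd_stat <- sd_step / sqrt(1 - phi^2)
  z[1] <- stats::rnorm(1, config$cloud_mu, sd_stat)
  eps <- stats::rnorm(n - 1, 0, sd_step)
  for (i in seq_len(n - 1)) {
    z[i + 1] <- config$cloud_mu + phi * (z[i] - config$cloud_mu) + eps[i]
  }
  0.10 + 0.92 * stats::plogis(z)
}

#' Visit-weighted calibration truth of a simulated campaign
#'
#' The generator's true panel ratio varies (slightly) with elevation inside
#' each 3 degree bin, so "the bin's true calibration function" is properly
#' the least-squares projection of the noiseless ratio onto the bin's
#' observed illumination design -- exactly what the binned OLS of
#' [fit_calibration()] estimates as its noise goes to zero. This computes
#' that projection from a campaign's `ratio_true` column, applying the same
#' row-filtering rules as the fit (illumination >= 15%, capped at 120%,
#' daytime only).
#'
#' @param panel The `panel` tibble of [generate_panel_campaign()].
#' @param site A [site_config()] (bin width).
#'
#' @return A tibble with `band`, `bin`, `slope`, `intercept`, `n`.
#' @export
true_calibration_projected <- function(panel, site) {
  stopifnot("ratio_true" %in% names(panel), inherits(site, "site_config"))
  panel |>
    dplyr::filter(!is.na(.data$illumination_pct),
                  .data$illumination_pct >= 15,
                  .data$elevation_deg >= 0) |>
    dplyr::mutate(
      illum = pmin(.data$illumination_pct, 120),
      bin = elevation_bin(.data$elevation_deg, site$elevation_bin_width_deg)
    ) |>
    dplyr::group_by(.data$band, .data$bin) |>
    dplyr::group_modify(function(d, key) {
      fit <- stats::lm(ratio_true ~ illum, data = d)
      tibble::tibble(
        slope = stats::coef(fit)[["illum"]],
        intercept = stats::coef(fit)[["(Intercept)"]],
        n = nrow(d)
      )
    }) |>
    dplyr::ungroup()
}

#' Simulate a white-panel cross-calibration campaign
#'
#' Generates a 1-min white-panel record over the configured campaign
#' (default 23 days): sky irradiance and panel radiance per band, where the
#' true panel ratio follows the configured fore-optic gain model plus
#' elevation-weighted noise, and a pyranometer channel from which percent
#' illumination is derived with the package's own clear-sky model.
#'
#' @param config A [generator_config()].
#'
#' @return A list: `panel`, a tibble of panel observations (`timestamp`,
#'   `band`, `r_standard`, `i_sky`, `illumination_pct`, `elevation_deg`,
#'   `pyr_Wm2`, plus the noiseless `ratio_true` truth column); `truth`, the
#'   analytic per-bin calibration truth for the bins the campaign covers.
#' @seealso [true_calibration()], [true_calibration_projected()]
#' @export
generate_panel_campaign <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  site <- config$site

  ts <- seq(
    as.POSIXct(paste(config$campaign_start, "00:00:00"), tz = "UTC"),
    by = "1 min", length.out = config$campaign_days * 1440
  )
  pos <- solar_position(site, ts)
  doy <- lubridate::yday(ts)
  modeled <- modeled_clear_sky(site, pos$elevation_deg, doy)

  keep <- modeled >= 1 # daylight
  ts <- ts[keep]
  el <- pos$elevation_deg[keep]
  modeled <- modeled[keep]
  n <- length(ts)

  illum_frac <- simulate_illumination(config, n, step_min = 1)
  global <- modeled * illum_frac
  pyr <- global * (1 + stats::rnorm(n, 0, 0.005))
  illum_pct <- percent_illumination(pyr, modeled)

  w <- gain_elevation_weight(el)
  band_const <- c("532" = 0.9, "570" = 1.0) # arbitrary machine-unit scale
  panel <- purrr::map(c(532, 570), function(b) {
    i_sky <- global * band_const[as.character(b)] *
      (1 + stats::rnorm(n, 0, 0.003))
    ratio_true <- true_cc_ratio(config, b, 100 * illum_frac, el)
    ratio <- ratio_true +
      stats::rnorm(n, 0, config$ratio_noise_sd * (1 + 2 * w))
    tibble::tibble(
      timestamp = ts, band = b,
      r_standard = i_sky * ratio, i_sky = i_sky,
      illumination_pct = illum_pct, elevation_deg = el, pyr_Wm2 = pyr,
      ratio_true = ratio_true
    )
  }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$timestamp, .data$band)

  bins <- sort(unique(elevation_bin(el, site$elevation_bin_width_deg)))
  list(panel = panel, truth = true_calibration(config, bins[bins >= 0]))
}

#' Daily ground truth of a synthetic season
#'
#' The deterministic daily layer every synthetic season is built on:
#' double-logistic NDVI phenology, fAPAR through the quadratic
#' NDVI-fAPAR curve, the phenology factor scaling the light-response
#' parameters, and the maturity/senescence stage labels. The fall
#' logistic's midpoint is placed so that the most negative NDVI second
#' derivative falls on `senescence_inflection_doy`.
#'
#' @param config A [generator_config()].
#'
#' @return A tibble with `date`, `doy`, `ndvi_true`, `fapar_true`,
#'   `amax_true`, `alpha_true`, `stage_true`.
#' @export
generate_season_truth <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed + 3L)
  dates <- seq(config$season_start, config$season_end, by = "day")
  doy <- as.integer(strftime(dates, "%j"))

  # fall midpoint offset: logistic curvature is most negative 1.317/k
  # before the midpoint
  df <- config$senescence_inflection_doy + 1.317 / config$fall_rate
  amp <- config$ndvi_peak - config$ndvi_base
  rise <- stats::plogis(config$spring_rate * (doy - config$spring_midpoint_doy))
  fall <- stats::plogis(config$fall_rate * (doy - df))
  ndvi <- config$ndvi_base + amp * rise * (1 - fall)

  fap <- pmin(pmax(-1.9596 * ndvi^2 + 2.954 * ndvi - 0.3484, 0.02), 1)
  fap_range <- range(fap)
  phen <- (fap - fap_range[1]) / max(diff(fap_range), 1e-9)
  phen <- pmin(pmax(phen, 0.05), 1)

  # day-to-day meteorological modulation of quantum yield: lognormal AR(1)
  nd <- length(dates)
  e <- numeric(nd)
  innov_sd <- config$alpha_day_sd * sqrt(1 - config$alpha_day_phi^2)
  e[1] <- stats::rnorm(1, 0, config$alpha_day_sd)
  for (i in seq_len(nd - 1)) {
    e[i + 1] <- config$alpha_day_phi * e[i] + stats::rnorm(1, 0, innov_sd)
  }

  tibble::tibble(
    date = dates, doy = doy,
    ndvi_true = ndvi,
    fapar_true = fap,
    amax_true = config$amax_peak * phen,
    # quantum yield collapses with the green canopy: outside the leafy
    # season a deciduous stand fixes essentially no carbon
    alpha_true = config$alpha_peak * phen * exp(e),
    stage_true = ifelse(doy <= config$senescence_inflection_doy,
                        "maturity", "senescence")
  )
}

#' Simulate a season of wireless-sensor-network canopy records
#'
#' Generates the 15-min WSN channel dialect (above/below-canopy PPFD pairs
#' and the pyranometer/quantum reflectance pairs) encoding the configured
#' NDVI/fAPAR phenology, with its own cloud realisation. Used by
#' [generate_season()] for its `wsn` component and directly wherever only
#' the canopy-phenology layer is needed (the channel ratios cancel the sky,
#' so the daily indices do not depend on the optical series' clouds).
#'
#' @param config A [generator_config()].
#'
#' @return A list: `wsn`, the 15-min channel tibble; `truth_daily`, the
#'   [generate_season_truth()] table; `transition_date`, the configured
#'   senescence inflection as a `Date`.
#' @export
generate_wsn_season <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed + 2L)
  site <- config$site
  daily <- generate_season_truth(config)

  ts <- seq(
    as.POSIXct(paste(config$season_start, "00:00:00"), tz = "UTC"),
    as.POSIXct(paste(config$season_end, "23:45:00"), tz = "UTC"),
    by = "15 min"
  )
  n <- length(ts)
  pos <- solar_position(site, ts)
  modeled <- modeled_clear_sky(site, pos$elevation_deg, lubridate::yday(ts))
  illum <- simulate_illumination(config, n, step_min = 15)
  global <- modeled * illum
  ppfd <- global * config$par_fraction * config$par_umol_per_j

  di <- match(lubridate::as_date(ts), daily$date)
  fap <- daily$fapar_true[di]
  ndvi <- daily$ndvi_true[di]
  r_can <- 0.03 + 0.02 * (1 - fap / max(fap))
  rs <- 0.08
  t_can <- pmin(pmax((1 - r_can - fap) / (1 - rs), 0), 1)
  rho_pyr <- r_can * (1 + ndvi) / (1 - ndvi)
  wnoise <- function() 1 + stats::rnorm(n, 0, 0.02)
  above <- ppfd * wnoise()
  wsn <- tibble::tibble(
    timestamp = ts,
    ppfd_above_down = above,
    ppfd_above_up = r_can * above * wnoise(),
    ppfd_below_down = t_can * above * wnoise(),
    ppfd_below_up = rs * t_can * above * wnoise(),
    pyr_down = global * wnoise(),
    pyr_up = rho_pyr * global * wnoise()
  )
  list(
    wsn = wsn, truth_daily = daily,
    transition_date = daily$date[match(config$senescence_inflection_doy,
                                       daily$doy)]
  )
}

# rectangular hyperbola GPP
hyperbola_gpp <- function(ppfd, amax, alpha) {
  ifelse(ppfd <= 0, 0, (amax * alpha * ppfd) / (amax + alpha * ppfd))
}

#' Simulate a full canopy/flux season with known ground truth
#'
#' Generates co-registered series at the study site: 1-min optical logger
#' records (per-band radiance/irradiance biased by the fore-optic gain
#' model, pyranometer, precipitation), 15-min wireless-sensor-network PPFD
#' records encoding the fAPAR/NDVI phenology, and 30-min flux records with
#' NEE built from the rectangular-hyperbola light response plus Q10
#' respiration and noise. A 30-min truth table holds the exact value of
#' every quantity the pipeline estimates.
#'
#' The true sPRI is coupled to true instantaneous LUE (facultative,
#' xanthophyll-style signal) during the whole season; during senescence it
#' gains an fAPAR-proportional constitutive drift and extra noise, so
#' stage-stratified correlations have the structure the stratified analysis
#' is designed to detect.
#'
#' @param config A [generator_config()].
#'
#' @return A list with tibbles `optical` (1-min: `timestamp`, `rad532`,
#'   `irr532`, `rad570`, `irr570`, `pyr_Wm2`, `precip_mm`), `wsn` (15-min
#'   WSN channel dialect), `flux` (30-min: `timestamp`, `nee`, `ustar`,
#'   `tair`, `ppfd`), `truth` (30-min truth), `truth_daily`
#'   ([generate_season_truth()] output plus the configured transition day),
#'   and `config`.
#' @export
generate_season <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed + 1L)
  site <- config$site
  daily <- generate_season_truth(config)

  ts <- seq(
    as.POSIXct(paste(config$season_start, "00:00:00"), tz = "UTC"),
    as.POSIXct(paste(config$season_end, "23:59:00"), tz = "UTC"),
    by = "1 min"
  )
  n <- length(ts)
  pos <- solar_position(site, ts)
  el <- pos$elevation_deg
  doy <- lubridate::yday(ts)
  date <- lubridate::as_date(ts)

  di <- match(date, daily$date)
  fap <- daily$fapar_true[di]
  amax <- daily$amax_true[di]
  alpha <- daily$alpha_true[di]

  # sky: clear-sky radiation modulated by AR(1) cloudiness (30-min blocks
  # expanded to 1 min so flux and optical records see the same sky)
  n30 <- ceiling(n / 30)
  illum30 <- simulate_illumination(config, n30, step_min = 30)
  illum_frac <- rep(illum30, each = 30)[seq_len(n)]
  modeled <- modeled_clear_sky(site, el, doy)
  global <- modeled * illum_frac
  ppfd <- global * config$par_fraction * config$par_umol_per_j

  # air temperature: seasonal + diurnal + slow noise
  hod <- lubridate::hour(ts) + lubridate::minute(ts) / 60
  tair30 <- stats::rnorm(n30, 0, 1)
  tair <- 1 + 16 * sin(pi * (doy - 110) / 185) +
    4 * sin(2 * pi * (hod - 9) / 24) + rep(tair30, each = 30)[seq_len(n)]

  # instantaneous truth
  gpp_true <- hyperbola_gpp(ppfd, amax, alpha)
  reco_true <- reco_model(tair, config$r10, config$q10)
  lue_inst <- amax * alpha / ((amax + alpha * ppfd) * fap)

  sen <- daily$stage_true[di] == "senescence"
  fap_tr <- daily$fapar_true[match(config$senescence_inflection_doy, daily$doy)]
  phen_n <- (fap - min(daily$fapar_true)) /
    max(diff(range(daily$fapar_true)), 1e-9)
  # canopy-scale nuisance scatter: AR(1) over 30-min blocks, persistence
  # 0.8 per step, stationary sd 1, scaled by canopy state
  z <- numeric(n30)
  z[1] <- stats::rnorm(1)
  innov <- stats::rnorm(n30 - 1, 0, sqrt(1 - 0.8^2))
  for (i in seq_len(n30 - 1)) z[i + 1] <- 0.8 * z[i] + innov[i]
  nuis <- rep(z, each = 30)[seq_len(n)] *
    config$spri_noise_sd * (0.6 + 0.4 * phen_n)
  spri_noise30 <- stats::rnorm(n30, 0, 1)
  # facultative (xanthophyll) coupling fades as the canopy thins:
  # constitutive pigment-pool/structure changes dilute the physiological
  # signal, so the LUE coupling carries a canopy-state weight while the
  # fAPAR drift term takes over during senescence
  fac_w <- 0.1 + 0.9 * phen_n
  spri_true <- config$spri0 + config$spri_lue_slope * fac_w * lue_inst + nuis +
    ifelse(sen, config$spri_sen_drift * (fap - fap_tr), 0) +
    ifelse(sen, config$spri_sen_noise_sd, 0) *
      rep(spri_noise30, each = 30)[seq_len(n)]
  # upper clamp keeps rho532 = rho570 (1+PRI)/(1-PRI) below 1
  spri_true <- pmin(pmax(spri_true, 0.02), 0.93)
  pri_true <- 2 * spri_true - 1
  rho570_true <- rep(config$rho570, n)
  rho532_true <- rho570_true * (1 + pri_true) / (1 - pri_true)

  # precipitation events
  precip <- numeric(n)
  n_ev <- stats::rpois(1, config$precip_events_per_day *
                         as.numeric(diff(range(date)) + 1))
  if (n_ev > 0) {
    starts <- sort(sample.int(n, n_ev))
    durs <- pmax(10, round(stats::rexp(n_ev, 1 / 60)))
    for (k in seq_len(n_ev)) {
      idx <- starts[k]:min(n, starts[k] + durs[k])
      precip[idx] <- precip[idx] + stats::rexp(length(idx), 2)
    }
  }
  wet <- precip > 0

  # optical channels: measured rho = true rho * cc ratio * BRDF azimuth
  # modulation (+ droplet noise)
  az <- pos$azimuth_deg
  band_const <- c("532" = 0.9, "570" = 1.0)
  mk_band <- function(b, rho_true) {
    irr <- global * band_const[as.character(b)] *
      (1 + stats::rnorm(n, 0, 0.003))
    cc <- true_cc_ratio(config, b, 100 * illum_frac, el)
    brdf <- 1 + config$az_amp[as.character(b)] * sin((az - 180) * pi / 180)
    rad <- rho_true * cc * brdf * irr *
      (1 + stats::rnorm(n, 0, config$rad_noise_sd)) *
      (1 + wet * stats::rnorm(n, 0, 0.25))
    list(irr = irr, rad = rad)
  }
  b532 <- mk_band(532, rho532_true)
  b570 <- mk_band(570, rho570_true)

  optical <- tibble::tibble(
    timestamp = ts,
    rad532 = b532$rad, irr532 = b532$irr,
    rad570 = b570$rad, irr570 = b570$irr,
    pyr_Wm2 = global * (1 + stats::rnorm(n, 0, 0.005)),
    precip_mm = precip
  )

  # WSN channels (15-min) from the daily canopy truth
  wsn <- generate_wsn_season(config)$wsn

  # 30-min flux records
  g30 <- rep(seq_len(n30), each = 30)[seq_len(n)]
  agg <- function(x) as.numeric(tapply(x, g30, mean))
  ppfd30 <- agg(ppfd)
  tair30s <- agg(tair)
  gpp30 <- agg(gpp_true)
  reco30 <- agg(reco_true)
  night30 <- ppfd30 < 5
  ustar <- exp(stats::rnorm(n30, log(ifelse(night30, 0.18, 0.35)), 0.45))
  flux <- tibble::tibble(
    timestamp = ts[seq(1, n, by = 30)][seq_len(n30)],
    nee = -gpp30 + reco30 + stats::rnorm(n30, 0, config$nee_noise_sd),
    ustar = ustar,
    tair = tair30s,
    ppfd = ppfd30
  )

  truth <- tibble::tibble(
    timestamp = flux$timestamp,
    elevation_deg = agg(el),
    illumination_pct = 100 * agg(illum_frac),
    ppfd = ppfd30,
    fapar_true = agg(fap),
    gpp_true = gpp30,
    reco_true = reco30,
    lue_true = agg(lue_inst),
    spri_true = agg(spri_true),
    rho532_true = agg(rho532_true),
    rho570_true = agg(rho570_true),
    amax_true = agg(amax),
    alpha_true = agg(alpha),
    stage_true = daily$stage_true[match(lubridate::as_date(flux$timestamp),
                                        daily$date)]
  )

  list(
    optical = optical, wsn = wsn, flux = flux,
    truth = truth,
    truth_daily = daily,
    transition_date = daily$date[match(config$senescence_inflection_doy,
                                       daily$doy)],
    config = config
  )
}
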