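#' Fraction of absorbed photosynthetically active radiation
#'
#' Canopy fAPAR from a radiation balance of the stand:
#' `fAPAR = 1 - t - r + t * rs`, where `t` is the fraction of incident PPFD
#' transmitted through the canopy, `r` the fraction reflected from the
#' canopy top, and `rs` the soil reflectance fraction (soil-reflected light
#' that re-enters the canopy is counted as absorbed). Values outside
#' \[0, 1\] can arise from sensor noise; they are returned unchanged so the
#' caller can flag them (see `fapar_physical()`).
#'
#' @param t Transmitted PPFD fraction (below/above canopy).
#' @param r Canopy-reflected PPFD fraction.
#' @param rs Soil reflectance fraction.
#'
#' @return fAPAR.
#' @examples
#' fapar(0.2, 0.05, 0.1)
#' @export
fapar <- function(t, r, rs) {
  1 - t - r + t * rs
}

#' @rdname fapar
#' @param fapar fAPAR values.
#' @return `fapar_physical()`: logical, `TRUE` where fAPAR is in \[0, 1\].
#' @export
fapar_physical <- function(fapar) {
  !is.na(fapar) & fapar >= 0 & fapar <= 1
}

#' Quadratic NDVI-fAPAR relationship
#'
#' Fits `fAPAR ~ NDVI + NDVI^2` by least squares on daily values. The
#' relationship between a broadband greenness index and absorbed light is
#' saturating (NDVI stops responding as the canopy closes), so a degree-2
#' polynomial is used rather than a straight line. Orientation: NDVI is the
#' predictor (x), fAPAR the response (y).
#'
#' @param ndvi Daily NDVI values.
#' @param fapar Paired daily fAPAR values.
#'
#' @return An object of class `ndvi_fapar_fit` wrapping the `lm`, with
#'   `tidy()`/`glance()` methods and a `predict()` method taking NDVI.
#' @export
ndvi_fapar_fit <- function(ndvi, fapar) {
  ok <- !is.na(ndvi) & !is.na(fapar)
  if (sum(ok) < 10) stop("need at least 10 paired daily values", call. = FALSE)
  if (stats::sd(ndvi[ok]) < 1e-10) {
    stop("NDVI series is degenerate (no variance)", call. = FALSE)
  }
  d <- tibble::tibble(ndvi = ndvi[ok], fapar = fapar[ok])
  fit <- stats::lm(fapar ~ ndvi + I(ndvi^2), data = d)
  structure(
    list(
      fit = fit,
      coefficients = c(
        intercept = unname(stats::coef(fit)[1]),
        linear = unname(stats::coef(fit)[2]),
        quadratic = unname(stats::coef(fit)[3])
      ),
      r2 = summary(fit)$r.squared,
      n = nrow(d),
      ndvi_range = range(d$ndvi)
    ),
    class = "ndvi_fapar_fit"
  )
}

#' @export
print.ndvi_fapar_fit <- function(x, ...) {
  co <- x$coefficients
  cat(sprintf(
    "<ndvi_fapar_fit> fAPAR = %.4f x^2 %+.4f x %+.4f  (x = NDVI), R2 = %.3f, n = %d\n",
    co["quadratic"], co["linear"], co["intercept"], x$r2, x$n
  ))
  invisible(x)
}

#' @rdname ndvi_fapar_fit
#' @param x,object An `ndvi_fapar_fit`.
#' @param newdata NDVI values at which to evaluate the polynomial.
#' @param ... Unused.
#' @export
predict.ndvi_fapar_fit <- function(object, newdata, ...) {
  co <- unname(object$coefficients)
  co[1] + co[2] * newdata + co[3] * newdata^2
}

#' @rdname ndvi_fapar_fit
#' @export
tidy.ndvi_fapar_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients)
  )
}

#' @rdname ndvi_fapar_fit
#' @export
glance.ndvi_fapar_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r2, nobs = x$n)
}

#' Detect the maturity-to-senescence transition from a daily NDVI series
#'
#' Smooths the daily NDVI series with a centred moving average, takes a
#' discrete second derivative (central second difference with a multi-day
#' step), and places the transition at the most negative curvature in the
#' post-peak part of the season -- the date at which the NDVI decline
#' accelerates fastest, i.e. the onset of leaf senescence. Days up to and
#' including the transition are labelled `maturity`, later days
#' `senescence`.
#'
#' The second-difference step `deriv_step` trades noise against locality:
#' a 1-day step amplifies daily NDVI noise ~`step^2`-fold relative to a
#' multi-day step, while any step much shorter than the senescence
#' transition itself (one to two weeks) leaves the located date unbiased.
#' The 3-day default matches the smoothing half-width.
#'
#' @param dates A `Date` vector (daily, sorted).
#' @param ndvi Daily NDVI values.
#' @param smooth_days Moving-average window, days (odd; default 7).
#' @param deriv_step Step of the central second difference, days.
#'
#' @return A list of class `phenology_stage` with `transition_date`,
#'   a `stages` tibble (`date`, `stage`), and `found` (FALSE when the series
#'   has no post-peak decline, in which case all days are `maturity`).
#' @export
phenology_transition <- function(dates, ndvi, smooth_days = 7,
                                 deriv_step = 3) {
  stopifnot(length(dates) == length(ndvi), smooth_days >= 3,
            deriv_step >= 1)
  if (length(dates) < 60) {
    stop("need a daily series covering at least 60 days", call. = FALSE)
  }
  ord <- order(dates)
  dates <- dates[ord]
  y <- ndvi[ord]

  k <- smooth_days
  sm <- stats::filter(y, rep(1 / k, k), sides = 2)
  sm <- as.numeric(sm)
  # central second difference with a multi-day step on the smoothed series
  h <- as.integer(deriv_step)
  n <- length(sm)
  d2 <- rep(NA_real_, n)
  idx <- (1 + h):(n - h)
  d2[idx] <- sm[idx + h] - 2 * sm[idx] + sm[idx - h]

  peak <- which.max(sm)
  post <- seq_along(sm) > peak
  cand <- which(post & !is.na(d2))

  decline <- length(cand) > 0 &&
    (max(sm, na.rm = TRUE) - sm[max(which(!is.na(sm)))]) >
      0.05 * diff(range(sm, na.rm = TRUE) + c(0, 1e-12))

  if (!decline || length(cand) == 0) {
    stages <- tibble::tibble(date = dates, stage = "maturity")
    return(structure(
      list(transition_date = as.Date(NA), stages = stages, found = FALSE),
      class = "phenology_stage"
    ))
  }
  tr_idx <- cand[which.min(d2[cand])]
  tr_date <- dates[tr_idx]
  stages <- tibble::tibble(
    date = dates,
    stage = ifelse(dates <= tr_date, "maturity", "senescence")
  )
  structure(
    list(transition_date = tr_date, stages = stages, found = TRUE),
    class = "phenology_stage"
  )
}

#' @export
print.phenology_stage <- function(x, ...) {
  if (x$found) {
    cat(sprintf("<phenology_stage> maturity -> senescence on %s (%d days)\n",
                format(x$transition_date), nrow(x$stages)))
  } else {
    cat("<phenology_stage> no senescence transition detected\n")
  }
  invisible(x)
}

#' Daily near-noon NDVI and fAPAR from WSN-style records
#'
#' Reduces sub-daily wireless-sensor-network records to one NDVI and fAPAR
#' value per day by averaging the 10:00-14:00 local-time window, avoiding
#' low-sun artifacts in the hemispherical ratios. Expects the WSN column
#' dialect: `ppfd_above_down` (incident), `ppfd_above_up` (canopy
#' reflected), `ppfd_below_down` (transmitted), `ppfd_below_up`
#' (soil reflected), `pyr_down`, `pyr_up`.
#'
#' @param data WSN records with a `timestamp` column (UTC) and the channel
#'   columns above.
#' @param site A [site_config()]; its `utc_offset_h` defines local time.
#'
#' @return A tibble with `date`, `ndvi`, `fapar` daily values.
#' @export
daily_canopy_indices <- function(data, site) {
  stopifnot(inherits(site, "site_config"))
  local_ts <- data$timestamp + site$utc_offset_h * 3600
  hr <- lubridate::hour(local_ts) + lubridate::minute(local_ts) / 60
  data |>
    dplyr::mutate(
      date = lubridate::as_date(local_ts),
      t = reflectance(.data$ppfd_below_down, .data$ppfd_above_down),
      r = reflectance(.data$ppfd_above_up, .data$ppfd_above_down),
      rs = reflectance(.data$ppfd_below_up, .data$ppfd_below_down),
      fapar = fapar(.data$t, .data$r, .data$rs),
      ndvi = broadband_ndvi(
        reflectance(.data$pyr_up, .data$pyr_down),
        reflectance(.data$ppfd_above_up, .data$ppfd_above_down)
      )
    ) |>
    dplyr::filter(hr >= 10, hr < 14) |>
    dplyr::group_by(.data$date) |>
    dplyr::summarise(
      ndvi = mean(.data$ndvi, na.rm = TRUE),
      fapar = mean(.data$fapar, na.rm = TRUE),
      .groups = "drop"
    )
}
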