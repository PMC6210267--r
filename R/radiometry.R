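#' Reflectance from paired radiance/irradiance channels
#'
#' Uncorrected reflectance at a waveband is the ratio of downward-looking
#' radiance to upward-looking irradiance, both in machine units (no
#' radiometric conversion is ever applied; all downstream quantities are
#' ratios, so machine units cancel).
#'
#' @param radiance Radiance channel, machine units (>= 0).
#' @param irradiance Irradiance channel, machine units.
#'
#' @return `radiance / irradiance`; `NA` where `irradiance <= 0`.
#' @examples
#' reflectance(c(0.05, 0, 1), c(1, 1, 0))
#' @export
reflectance <- function(radiance, irradiance) {
  out <- radiance / irradiance
  out[is.na(irradiance) | irradiance <= 0] <- NA_real_
  out
}

#' Photochemical reflectance index and its scaled form
#'
#' `pri()` is the normalized difference of reflectance at 532 nm (the
#' xanthophyll-sensitive band) and 570 nm (the reference band):
#' `(rho532 - rho570) / (rho532 + rho570)`. `spri()` maps it into the 0-1
#' range used by most vegetation indices: `(1 + PRI) / 2`.
#'
#' @param rho532,rho570 Reflectance at 532 nm and 570 nm.
#' @param pri PRI values in `[-1, 1]`.
#'
#' @return `pri()`: PRI in `[-1, 1]`, `NA` where the band sum is not
#'   positive. `spri()`: scaled PRI in `[0, 1]`.
#' @examples
#' pri(0.03, 0.05)
#' spri(pri(0.03, 0.05))
#' @export
pri <- function(rho532, rho570) {
  denom <- rho532 + rho570
  out <- (rho532 - rho570) / denom
  out[is.na(denom) | denom <= 0] <- NA_real_
  out
}

#' @rdname pri
#' @export
spri <- function(pri) {
  (1 + pri) / 2
}

#' Broadband NDVI from pyranometer and quantum-sensor pairs
#'
#' A broadband analogue of NDVI built from two hemispherical reflectances
#' measured above the canopy: `rho_pyr`, the upwelling:downwelling ratio of a
#' pyranometer pair (total shortwave, standing in for the near-infrared-rich
#' band), and `rho_ppfd`, the same ratio from a quantum-sensor pair (PAR,
#' strongly absorbed by green canopies):
#' `NDVI = (rho_pyr - rho_ppfd) / (rho_pyr + rho_ppfd)`.
#'
#' @param rho_pyr Pyranometer (shortwave) reflectance.
#' @param rho_ppfd Quantum-sensor (PAR) reflectance.
#'
#' @return Broadband NDVI; `NA` where the denominator is not positive.
#' @examples
#' broadband_ndvi(0.15, 0.05)
#' @export
broadband_ndvi <- function(rho_pyr, rho_ppfd) {
  denom <- rho_pyr + rho_ppfd
  out <- (rho_pyr - rho_ppfd) / denom
  out[is.na(denom) | denom <= 0] <- NA_real_
  out
}

#' Flag samples around precipitation events
#'
#' Water droplets on the flat cosine diffusers of the upward-looking sensors
#' cause significant signal noise, so optical samples recorded during a
#' precipitation event -- and within a guard window before and after it --
#' are removed. An event is any run of timestamps with positive
#' precipitation.
#'
#' @param data A data frame with a `timestamp` column (POSIXct).
#' @param precip A data frame with `timestamp` and `precip_mm` columns,
#'   co-registered in time with `data` (need not share its sampling grid).
#' @param window_min Guard window applied on both sides of each event,
#'   minutes.
#'
#' @return `data` with a logical `precip_flag` column; `TRUE` marks rows to
#'   drop. With an empty or all-zero precipitation series every row is kept.
#' @export
filter_precipitation <- function(data, precip, window_min = 30) {
  stopifnot("timestamp" %in% names(data))
  flag <- rep(FALSE, nrow(data))
  if (!is.null(precip) && nrow(precip) > 0) {
    wet <- precip[!is.na(precip$precip_mm) & precip$precip_mm > 0, , drop = FALSE]
    if (nrow(wet) > 0) {
      # merge wet timestamps into events: consecutive wet rows closer than
      # the guard window form one interval
      ts <- sort(unique(as.numeric(wet$timestamp)))
      gap <- c(Inf, diff(ts))
      ev_id <- cumsum(gap > window_min * 60)
      starts <- tapply(ts, ev_id, min) - window_min * 60
      ends <- tapply(ts, ev_id, max) + window_min * 60
      tnum <- as.numeric(data$timestamp)
      for (k in seq_along(starts)) {
        flag <- flag | (tnum >= starts[[k]] & tnum <= ends[[k]])
      }
    }
  }
  dplyr::mutate(data, precip_flag = flag)
}

#' Average a series into half-hour bins
#'
#' Averages value columns over half-open windows `[t, t + 30 min)` aligned
#' to :00/:30, the resolution of the eddy-covariance system. A window must
#' contain at least `min_coverage` of its expected samples (inferred from
#' the series' median sampling interval) for its mean to be reported;
#' sparser windows are returned as `NA` so optical dropouts cannot
#' masquerade as canopy signal.
#'
#' @param data A data frame with `timestamp` plus numeric columns.
#' @param cols <tidy-select> Columns to average; defaults to every numeric
#'   column.
#' @param min_coverage Minimum fraction of expected samples per window.
#'
#' @return A tibble with one row per half-hour window (`timestamp` = window
#'   start) and the per-window means.
#' @export
bin_halfhour <- function(data, cols = dplyr::where(is.numeric),
                         min_coverage = 0.5) {
  stopifnot("timestamp" %in% names(data))
  dt <- stats::median(diff(sort(unique(as.numeric(data$timestamp)))))
  expected <- if (is.finite(dt) && dt > 0) max(1, round(30 * 60 / dt)) else 1

  data |>
    dplyr::mutate(timestamp = lubridate::floor_date(.data$timestamp, "30 minutes")) |>
    dplyr::group_by(.data$timestamp) |>
    dplyr::summarise(
      dplyr::across(
        {{ cols }},
        ~ if (sum(!is.na(.x)) >= min_coverage * expected) {
          mean(.x, na.rm = TRUE)
        } else {
          NA_real_
        }
      ),
      .groups = "drop"
    )
}

#' Derive per-sample reflectance, PRI and sPRI columns
#'
#' Convenience wrapper that maps the raw logger columns (`rad532`, `irr532`,
#' `rad570`, `irr570`) to `rho532`, `rho570`, `pri` and `spri` using
#' [reflectance()] and [pri()].
#'
#' @param data A data frame with the four raw channel columns.
#' @return `data` with `rho532`, `rho570`, `pri`, `spri` columns appended.
#' @export
srs_reflectance <- function(data) {
  stopifnot(all(c("rad532", "irr532", "rad570", "irr570") %in% names(data)))
  data |>
    dplyr::mutate(
      rho532 = reflectance(.data$rad532, .data$irr532),
      rho570 = reflectance(.data$rad570, .data$irr570),
      pri = pri(.data$rho532, .data$rho570),
      spri = spri(.data$pri)
    )
}
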