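#' Theoretical radiance/irradiance ratio of an ideal diffuse reflector
#'
#' For a perfectly Lambertian surface, radiance is the reflected irradiance
#' spread uniformly over the projected hemisphere, so the radiance to
#' irradiance ratio of an ideal (reflectance 1) diffuse reflector is
#' `1 / pi` sr-1, about 0.318. Cross-calibration ratios measured over a
#' near-perfect white standard panel should scatter around this value; it is
#' the physical sanity check on a calibration campaign.
#'
#' @param panel_reflectance Reflectance factor of the panel (1 for an ideal
#'   reflector; 0.99 for a typical sintered-PTFE white standard).
#'
#' @return The expected radiance/irradiance ratio, sr-1.
#' @examples
#' lambertian_ratio() # 1/pi ~ 0.318
#' @export
lambertian_ratio <- function(panel_reflectance = 1) {
  stopifnot(panel_reflectance > 0, panel_reflectance <= 1)
  panel_reflectance / pi
}

#' Fit white-panel cross-calibration functions
#'
#' Radiance and irradiance fore-optics respond differently to the diffuse
#' fraction of skylight: under overcast skies the restricted-field-of-view
#' radiance sensor and the hemispherical irradiance sensor see a more similar
#' light field than under direct sun, and the mismatch also varies with
#' solar elevation. Cross-calibration regresses the white-panel ratio
#' `r_standard / i_sky` on percent illumination separately within each
#' 3 degree solar-elevation bin and waveband, yielding a set of linear
#' calibration functions later evaluated by [correction_ratio()].
#'
#' @param panel A data frame of white-panel observations with columns
#'   `band` (532 or 570), `r_standard`, `i_sky`, `illumination_pct`,
#'   `elevation_deg`. Rows with non-positive `i_sky` or missing illumination
#'   are dropped; illumination is capped at 120% and values below 15% are
#'   excluded so every stored fit range lies inside \[15, 120\]%.
#' @param site A [site_config()]; supplies the elevation bin width.
#' @param min_n Minimum number of observations for a bin to be retained.
#'
#' @return A `pri_calibration` object: a tibble with one row per retained
#'   (band, bin) holding `slope`, `intercept`, `n`, `r2`, `illum_min`,
#'   `illum_max` and the bin's lower edge, plus metadata attributes.
#' @seealso [correction_ratio()], [apply_calibration()],
#'   [write_calibration()]
#' @export
fit_calibration <- function(panel, site, min_n = 20) {
  stopifnot(inherits(site, "site_config"))
  need <- c("band", "r_standard", "i_sky", "illumination_pct", "elevation_deg")
  if (!all(need %in% names(panel))) {
    stop("`panel` must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(panel) == 0) stop("`panel` is empty", call. = FALSE)
  bw <- site$elevation_bin_width_deg

  obs <- panel |>
    dplyr::filter(
      .data$i_sky > 0,
      !is.na(.data$illumination_pct), .data$illumination_pct >= 15,
      !is.na(.data$elevation_deg), .data$elevation_deg >= 0
    ) |>
    dplyr::mutate(
      ratio = .data$r_standard / .data$i_sky,
      illum = pmin(.data$illumination_pct, 120),
      bin = elevation_bin(.data$elevation_deg, bw)
    )
  if (nrow(obs) == 0) stop("no usable panel observations", call. = FALSE)

  fits <- obs |>
    dplyr::group_by(.data$band, .data$bin) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < min_n) return(tibble::tibble())
      if (stats::sd(d$illum) < 1e-8) {
        warning(sprintf(
          "band %s bin %d: degenerate illumination spread; bin omitted",
          key$band, key$bin
        ), call. = FALSE)
        return(tibble::tibble())
      }
      fit <- stats::lm(ratio ~ illum, data = d)
      tibble::tibble(
        slope = stats::coef(fit)[["illum"]],
        intercept = stats::coef(fit)[["(Intercept)"]],
        n = nrow(d),
        r2 = summary(fit)$r.squared,
        illum_min = min(d$illum),
        illum_max = max(d$illum)
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(bin_lower = .data$bin * bw, .after = "bin")

  if (nrow(fits) == 0) {
    stop("no calibration bin met the minimum-n rule", call. = FALSE)
  }
  structure(fits,
    class = c("pri_calibration", class(fits)),
    bin_width_deg = bw, min_n = min_n
  )
}

#' @export
print.pri_calibration <- function(x, ...) {
  cat(sprintf(
    "<pri_calibration> %d calibration functions (%d bands, %g deg bins)\n",
    nrow(x), dplyr::n_distinct(x$band), attr(x, "bin_width_deg")
  ))
  NextMethod()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_calibration
#' @param x A `pri_calibration` object.
#' @param ... Unused.
#' @export
tidy.pri_calibration <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname fit_calibration
#' @export
glance.pri_calibration <- function(x, ...) {
  tibble::tibble(
    n_functions = nrow(x),
    n_bands = dplyr::n_distinct(x$band),
    bin_width_deg = attr(x, "bin_width_deg"),
    elevation_min_deg = min(x$bin_lower),
    elevation_max_deg = max(x$bin_lower) + attr(x, "bin_width_deg"),
    median_r2 = stats::median(x$r2),
    median_intercept = stats::median(x$intercept)
  )
}

#' Evaluate cross-calibration ratios
#'
#' Looks up the calibration function for each observation and evaluates it
#' at the observation's percent illumination. In `"diurnal"` mode the
#' function of the bin containing the observation's own solar elevation is
#' used, tracking the sun through the day; in `"midday"` mode every
#' observation of a day uses the bin containing that day's solar-noon
#' elevation. Illumination is capped at 120% and clamped to the bin's fitted
#' range (the fitted slopes are negative, so extrapolation could drive the
#' ratio through zero). Elevations falling in a bin with no retained
#' function (e.g. above the calibration campaign's maximum elevation) fall
#' back to the nearest retained bin and are flagged.
#'
#' @param calset A `pri_calibration` from [fit_calibration()].
#' @param band Waveband, 532 or 570 (scalar or vector).
#' @param elevation_deg Solar elevation of each observation, degrees.
#' @param illumination_pct Percent illumination of each observation.
#' @param mode `"diurnal"` or `"midday"`.
#' @param noon_elevation_deg Solar-noon elevation of each observation's day;
#'   required in `"midday"` mode.
#'
#' @return A tibble with `ratio`, `bin_used`, `fallback` (nearest-bin used)
#'   and `clamped` (illumination outside the fitted range) columns. Night
#'   elevations yield `NA` ratios.
#' @export
correction_ratio <- function(calset, band, elevation_deg, illumination_pct,
                             mode = c("diurnal", "midday"),
                             noon_elevation_deg = NULL) {
  stopifnot(inherits(calset, "pri_calibration"), nrow(calset) > 0)
  mode <- match.arg(mode)
  bw <- attr(calset, "bin_width_deg")

  el <- if (mode == "midday") {
    if (is.null(noon_elevation_deg)) {
      stop("`noon_elevation_deg` is required in midday mode", call. = FALSE)
    }
    noon_elevation_deg
  } else {
    elevation_deg
  }

  n <- max(length(band), length(el), length(illumination_pct))
  band <- rep_len(band, n)
  el <- rep_len(el, n)
  illum <- pmin(rep_len(illumination_pct, n), 120)
  want <- elevation_bin(el, bw)

  out <- tibble::tibble(
    ratio = NA_real_, bin_used = NA_integer_,
    fallback = FALSE, clamped = FALSE, .rows = n
  )
  for (b in unique(stats::na.omit(band))) {
    cal_b <- calset[calset$band == b, , drop = FALSE]
    if (nrow(cal_b) == 0) next
    sel <- which(!is.na(band) & band == b & !is.na(want) & want >= 0 &
                   !is.na(illum))
    if (length(sel) == 0) next
    # nearest retained bin per requested bin
    idx <- vapply(want[sel], function(w) which.min(abs(cal_b$bin - w)),
                  integer(1))
    used <- cal_b$bin[idx]
    lo <- cal_b$illum_min[idx]
    hi <- cal_b$illum_max[idx]
    il <- pmin(pmax(illum[sel], lo), hi)
    out$ratio[sel] <- cal_b$slope[idx] * il + cal_b$intercept[idx]
    out$bin_used[sel] <- as.integer(used)
    out$fallback[sel] <- used != want[sel]
    out$clamped[sel] <- il != illum[sel]
  }
  out
}

#' Correct reflectance with a cross-calibration ratio
#'
#' Corrected reflectance divides the uncorrected radiance/irradiance ratio
#' by the white-panel cross-calibration ratio measured under matching
#' illumination and solar-elevation conditions:
#' `rho_corrected = (r_target / i_sky) / (r_standard / i_sky)`. The panel's
#' 0.99 reflectance factor is deliberately not divided out; the corrected
#' value is a reflectance factor relative to the white standard, and the
#' index algebra downstream is ratio-based.
#'
#' @param rho_uncorrected Uncorrected reflectance (machine-unit ratio).
#' @param ratio Cross-calibration ratio (> 0).
#'
#' @return Corrected reflectance; `NA` where `ratio <= 0`.
#' @examples
#' correct_reflectance(0.0318, 0.318)
#' @export
correct_reflectance <- function(rho_uncorrected, ratio) {
  out <- rho_uncorrected / ratio
  out[is.na(ratio) | ratio <= 0] <- NA_real_
  out
}

#' Apply diurnal or midday cross-calibration to a deployment series
#'
#' End-to-end correction of a canopy deployment: computes solar position for
#' each timestamp, derives percent illumination from the measured
#' pyranometer channel and the clear-sky model (unless an
#' `illumination_pct` column is already present), evaluates the per-band
#' calibration functions and rewrites `rho532`, `rho570`, `pri`, `spri`
#' as corrected values.
#'
#' @param data A data frame with `timestamp`, `rho532`, `rho570` and either
#'   `illumination_pct` or a measured global-radiation column `pyr_Wm2`.
#' @param calset A `pri_calibration`.
#' @param site A [site_config()].
#' @param mode `"diurnal"` or `"midday"` (see [correction_ratio()]).
#'
#' @return `data` with corrected `rho532`, `rho570`, `pri`, `spri`, plus
#'   `elevation_deg`, `illumination_pct`, `corrected` (the mode) and
#'   `cal_flag` (fallback or clamped lookup on either band) columns.
#' @export
apply_calibration <- function(data, calset, site,
                              mode = c("diurnal", "midday")) {
  mode <- match.arg(mode)
  stopifnot(all(c("timestamp", "rho532", "rho570") %in% names(data)))

  pos <- solar_position(site, data$timestamp)
  data$elevation_deg <- pos$elevation_deg
  if (!"illumination_pct" %in% names(data)) {
    if (!"pyr_Wm2" %in% names(data)) {
      stop("need `illumination_pct` or a measured `pyr_Wm2` column",
           call. = FALSE)
    }
    modeled <- modeled_clear_sky(site, pos$elevation_deg,
                                 doy = lubridate::yday(pos$timestamp))
    data$illumination_pct <- percent_illumination(data$pyr_Wm2, modeled)
  }

  c532 <- correction_ratio(calset, 532, pos$elevation_deg,
                           data$illumination_pct, mode,
                           pos$noon_elevation_deg)
  c570 <- correction_ratio(calset, 570, pos$elevation_deg,
                           data$illumination_pct, mode,
                           pos$noon_elevation_deg)

  data |>
    dplyr::mutate(
      rho532 = correct_reflectance(.data$rho532, c532$ratio),
      rho570 = correct_reflectance(.data$rho570, c570$ratio),
      pri = pri(.data$rho532, .data$rho570),
      spri = spri(.data$pri),
      corrected = mode,
      cal_flag = c532$fallback | c570$fallback | c532$clamped | c570$clamped
    )
}

#' Read/write calibration function sets
#'
#' Calibration sets are serialized as plain CSV (band, bin, bin lower edge,
#' slope, intercept, n, R2, illumination fit range) with the bin width and
#' minimum-n rule in a `#`-prefixed header line, so a calibration campaign
#' fitted once can be applied to any later deployment.
#'
#' @param calset A `pri_calibration`.
#' @param path File path.
#' @return `write_calibration()` returns `calset` invisibly;
#'   `read_calibration()` returns a `pri_calibration`.
#' @export
write_calibration <- function(calset, path) {
  stopifnot(inherits(calset, "pri_calibration"))
  header <- sprintf("# priflux calibration v1 bin_width_deg=%g min_n=%d",
                    attr(calset, "bin_width_deg"), attr(calset, "min_n"))
  writeLines(header, path)
  suppressMessages(
    readr::write_csv(tibble::as_tibble(unclass(calset)), path, append = TRUE,
                     col_names = TRUE)
  )
  invisible(calset)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  header <- readLines(path, n = 1)
  m <- regmatches(header, regexec(
    "bin_width_deg=([0-9.]+) min_n=([0-9]+)", header))[[1]]
  if (length(m) != 3) stop("not a priflux calibration file", call. = FALSE)
  tab <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  attr(tab, "spec") <- NULL
  attr(tab, "problems") <- NULL
  tab$bin <- as.integer(tab$bin)
  tab$n <- as.integer(tab$n)
  structure(tab,
    class = c("pri_calibration", class(tab)),
    bin_width_deg = as.numeric(m[2]), min_n = as.integer(m[3])
  )
}
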