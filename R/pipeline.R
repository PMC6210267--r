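#' Run the full season analysis pipeline
#'
#' Chains every processing stage on a season of co-registered records:
#'
#' 1. optical: precipitation filter, per-minute reflectance/PRI,
#'    cross-calibration correction, 30-min binning;
#' 2. canopy: daily near-noon NDVI/fAPAR, quadratic NDVI-fAPAR fit,
#'    second-derivative phenology transition;
#' 3. flux: u* filter, nighttime respiration regression, GPP partitioning,
#'    2-day light-response fits (apparent quantum yield trajectory);
#' 4. efficiency: LUE = GPP/APAR, stage-stratified correlations, and the
#'    sPRI- and alpha-driven LUE models of GPP.
#'
#' Comparisons against the apparent quantum yield are computed at the
#' quantity's native 2-day-window resolution (window means of the 30-min
#' series); all other correlations are at 30 min.
#'
#' @param optical 1-min optical logger records (`timestamp`, `rad532`,
#'   `irr532`, `rad570`, `irr570`, `pyr_Wm2`, `precip_mm`).
#' @param wsn WSN records (see [daily_canopy_indices()]).
#' @param flux 30-min flux records (`timestamp`, `nee`, `ustar`, `tair`,
#'   `ppfd`).
#' @param calset A `pri_calibration` from [fit_calibration()].
#' @param site A [site_config()].
#' @param mode Correction mode passed to [apply_calibration()].
#' @param apar_floor APAR floor for LUE, micro-mol m-2 s-1.
#'
#' @return A list of class `priflux_season`: `data` (the 30-min analysis
#'   table; its `alpha` column is the reliability-screened, running-median
#'   filtered trajectory), `windows` (per-window light-response fits, raw
#'   and filtered), `phenology`,
#'   `ndvi_fapar`, `reco`, `models` (proxy-driven LUE models and their
#'   GPP predictions' r2), and `correlations` (stratified r2 table).
#' @export
run_season_pipeline <- function(optical, wsn, flux, calset, site,
                                mode = "diurnal", apar_floor = 50) {
  # --- optical chain -------------------------------------------------
  opt <- optical |>
    filter_precipitation(optical[, c("timestamp", "precip_mm")]) |>
    dplyr::filter(!.data$precip_flag) |>
    srs_reflectance() |>
    apply_calibration(calset, site, mode = mode)
  spri30 <- opt |>
    dplyr::select("timestamp", "spri", "pri", "rho532", "rho570") |>
    bin_halfhour()

  # --- canopy chain --------------------------------------------------
  daily <- daily_canopy_indices(wsn, site)
  phen <- phenology_transition(daily$date, daily$ndvi)
  nf_fit <- ndvi_fapar_fit(daily$ndvi, daily$fapar)

  # --- flux chain ----------------------------------------------------
  fl <- ustar_filter(flux, site$ustar_threshold_ms)
  reco_fit <- nighttime_reco(fl)
  fl$reco <- reco_fit$reco
  part <- partition_gpp(fl$nee, fl$reco)
  fl$gpp <- part$gpp
  fl$gpp[fl$ustar_flag] <- NA_real_
  windows <- dplyr::arrange(fit_light_response_windows(fl), .data$window)
  # outlier-robust quantum-yield trajectory: keep every converged,
  # in-bounds window -- including low-signal shoulder-season windows whose
  # alpha is individually imprecise but which anchor the seasonal envelope
  # -- and pass a 3-window running median over the series to remove
  # isolated fit jumps without smoothing the seasonal trend
  a_rel <- ifelse(windows$converged & windows$within_bounds,
                  windows$alpha, NA_real_)
  idx <- which(is.finite(a_rel))
  if (length(idx) >= 5) {
    a_rel[idx] <- stats::runmed(a_rel[idx], 5, endrule = "median")
  }
  windows$alpha_filtered <- a_rel

  # --- 30-min analysis table -----------------------------------------
  d0 <- min(lubridate::as_date(flux$timestamp))
  stage_of <- function(dates) {
    s <- phen$stages$stage[match(dates, phen$stages$date)]
    s
  }
  data30 <- fl |>
    dplyr::left_join(spri30, by = "timestamp") |>
    dplyr::mutate(
      date = lubridate::as_date(.data$timestamp),
      window = d0 + 2 * (as.numeric(date - d0) %/% 2)
    ) |>
    dplyr::left_join(dplyr::select(daily, "date", "ndvi", "fapar"),
                     by = "date") |>
    dplyr::left_join(
      dplyr::select(windows, "window", alpha = "alpha_filtered"),
      by = "window"
    ) |>
    dplyr::mutate(
      apar = .data$fapar * .data$ppfd,
      lue = lue(.data$gpp, .data$apar, apar_floor),
      stage = stage_of(.data$date)
    )

  # --- correlations --------------------------------------------------
  cors <- dplyr::bind_rows(
    stratified_correlation(data30, "spri", "lue"),
    stratified_correlation(data30, "spri", "fapar"),
    stratified_correlation(data30, "lue", "fapar")
  )
  # alpha comparisons at the 2-day-window scale
  # flux-weighted window LUE (sum GPP / sum APAR), the standard period
  # definition; much less noise-prone than averaging 30-min ratios
  wdat <- data30 |>
    dplyr::group_by(.data$window) |>
    dplyr::summarise(
      alpha = dplyr::first(.data$alpha),
      lue = {
        ok <- is.finite(.data$gpp) & is.finite(.data$apar) &
          .data$apar >= apar_floor
        if (sum(ok) >= 5) sum(.data$gpp[ok]) / sum(.data$apar[ok]) else NA_real_
      },
      spri = mean(.data$spri, na.rm = TRUE),
      stage = names(which.max(table(.data$stage))),
      .groups = "drop"
    )
  cors <- dplyr::bind_rows(
    cors,
    stratified_correlation(wdat, "alpha", "lue"),
    stratified_correlation(wdat, "spri", "alpha")
  )

  # --- LUE models ----------------------------------------------------
  models <- purrr::map(c("spri", "alpha"), function(px) {
    ok <- tryCatch(fit_lue_model(data30, proxy = px),
                   error = function(e) NULL)
    if (is.null(ok)) return(NULL)
    pred <- predict_gpp(ok, data30[[px]], data30$apar)
    sel <- is.finite(pred) & is.finite(data30$gpp)
    tibble::tibble(
      proxy = px,
      slope = ok$slope, intercept = ok$intercept,
      lue_r2 = ok$r2, lue_p = ok$p_value, n = ok$n,
      gpp_r2 = stats::cor(pred[sel], data30$gpp[sel])^2
    )
  }) |>
    purrr::compact() |>
    dplyr::bind_rows()

  structure(
    list(
      data = data30, windows = windows, phenology = phen,
      ndvi_fapar = nf_fit, reco = reco_fit[c("r10", "q10", "n_night")],
      models = models, correlations = cors, mode = mode
    ),
    class = "priflux_season"
  )
}

#' @export
print.priflux_season <- function(x, ...) {
  cat(sprintf("<priflux_season> %d half-hour records, %s correction\n",
              nrow(x$data), x$mode))
  if (x$phenology$found) {
    cat(sprintf("  senescence transition: %s\n",
                format(x$phenology$transition_date)))
  }
  cat("  proxy-driven LUE models:\n")
  for (i in seq_len(nrow(x$models))) {
    cat(sprintf("    %-6s LUE R2 = %.2f, modeled-GPP R2 = %.2f (n %d)\n",
                x$models$proxy[i], x$models$lue_r2[i], x$models$gpp_r2[i],
                x$models$n[i]))
  }
  invisible(x)
}

#' Plain-text season report
#'
#' Writes the stratified-correlation and model-comparison tables of a
#' [run_season_pipeline()] result to a CSV file and returns a one-block
#' text summary.
#'
#' @param result A `priflux_season`.
#' @param path Optional CSV path for the combined results table.
#' @return The combined results tibble, invisibly.
#' @export
season_report <- function(result, path = NULL) {
  stopifnot(inherits(result, "priflux_season"))
  tab <- dplyr::bind_rows(
    dplyr::mutate(result$correlations, kind = "correlation"),
    result$models |>
      dplyr::transmute(
        x = .data$proxy, y = "gpp", scope = "season",
        r2 = .data$gpp_r2, p_value = NA_real_, n = .data$n,
        kind = "lue_model"
      )
  )
  if (!is.null(path)) readr::write_csv(tab, path)
  invisible(tab)
}
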