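#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot cross-calibration functions
#'
#' One fitted line per solar-elevation bin, per waveband, over the bin's
#' fitted illumination range -- the classic calibration-function figure:
#' steeper (more negative) slopes at low elevations, near-flat functions
#' near solar noon, intercepts scattered around the Lambertian 1/pi.
#'
#' @param object A `pri_calibration`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pri_calibration <- function(object, ...) {
  seg <- tibble::as_tibble(unclass(object)) |>
    dplyr::mutate(
      y_min = .data$slope * .data$illum_min + .data$intercept,
      y_max = .data$slope * .data$illum_max + .data$intercept,
      bin_label = sprintf("%g-%g deg", .data$bin_lower,
                          .data$bin_lower + attr(object, "bin_width_deg"))
    )
  ggplot2::ggplot(seg) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$illum_min, xend = .data$illum_max,
      y = .data$y_min, yend = .data$y_max,
      colour = .data$bin_lower, group = .data$bin_label
    )) +
    ggplot2::geom_hline(yintercept = lambertian_ratio(0.99),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::facet_wrap(ggplot2::vars(.data$band), labeller = "label_both") +
    ggplot2::scale_colour_viridis_c(name = "elevation (deg)") +
    ggplot2::labs(
      x = "illumination (%)", y = "cross-calibration ratio",
      title = "White-panel cross-calibration functions",
      subtitle = "dashed: ideal Lambertian panel ratio 0.99/pi"
    )
}

#' Diurnal sPRI correction comparison
#'
#' Overlays uncorrected, midday-corrected and diurnally corrected sPRI for
#' one or more days, optionally with a reference (truth or spectrometer)
#' series -- the figure that shows the diurnal correction recovering the
#' morning/evening pattern that the midday correction distorts.
#'
#' @param uncorrected,midday,diurnal Data frames with `timestamp` and
#'   `spri` columns.
#' @param reference Optional reference data frame (`timestamp`, `spri`).
#' @return A ggplot.
#' @export
plot_correction_comparison <- function(uncorrected, midday, diurnal,
                                       reference = NULL) {
  grab <- function(d, lab) {
    tibble::tibble(timestamp = d$timestamp, spri = d$spri, series = lab)
  }
  dat <- dplyr::bind_rows(
    grab(uncorrected, "uncorrected"),
    grab(midday, "midday corrected"),
    grab(diurnal, "diurnal corrected"),
    if (!is.null(reference)) grab(reference, "reference")
  )
  ggplot2::ggplot(dat, ggplot2::aes(.data$timestamp, .data$spri,
                                    colour = .data$series)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = NULL, y = "sPRI", colour = NULL,
                  title = "Effect of cross-calibration on diurnal sPRI")
}

#' Plot a light-response fit
#'
#' Observed NEE against PPFD with the fitted rectangular hyperbola (plus
#' mean respiration) overlaid.
#'
#' @param object A `light_response`.
#' @param data The composite-diurnal window the fit was run on (`nee`,
#'   `ppfd`, `tair`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.light_response <- function(object, data, ...) {
  stopifnot(all(c("nee", "ppfd", "tair") %in% names(data)))
  grid <- tibble::tibble(
    ppfd = seq(0, max(data$ppfd, na.rm = TRUE), length.out = 200)
  )
  grid$nee <- -hyperbola_gpp(grid$ppfd, object$amax, object$alpha) +
    reco_model(mean(data$tair, na.rm = TRUE), object$r10, object$q10)
  ggplot2::ggplot(data, ggplot2::aes(.data$ppfd, .data$nee)) +
    ggplot2::geom_point(alpha = 0.6, na.rm = TRUE) +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::labs(
      x = "PPFD (umol m-2 s-1)", y = "NEE (umol m-2 s-1)",
      title = sprintf("Light response: Amax %.1f, alpha %.3f",
                      object$amax, object$alpha)
    )
}

#' Seasonal overview of a pipeline result
#'
#' Daily means of sPRI, LUE and apparent quantum yield with the detected
#' senescence transition marked.
#'
#' @param object A `priflux_season` from [run_season_pipeline()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.priflux_season <- function(object, ...) {
  daily <- object$data |>
    dplyr::group_by(.data$date) |>
    dplyr::summarise(
      sPRI = mean(.data$spri, na.rm = TRUE),
      LUE = mean(.data$lue, na.rm = TRUE),
      alpha = mean(.data$alpha, na.rm = TRUE),
      .groups = "drop"
    ) |>
    tidyr::pivot_longer(-"date", names_to = "series")
  p <- ggplot2::ggplot(daily, ggplot2::aes(.data$date, .data$value)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_wrap(ggplot2::vars(.data$series), ncol = 1,
                        scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Season: sPRI, LUE and apparent quantum yield")
  if (object$phenology$found) {
    p <- p + ggplot2::geom_vline(
      xintercept = object$phenology$transition_date,
      linetype = "dashed", colour = "grey40"
    )
  }
  p
}
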