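#' Read and write logger-style CSV time series
#'
#' All pipeline inputs share one CSV dialect: comma-separated, ISO 8601
#' timestamps (parsed as UTC), missing values as empty cells. Three column
#' sets are recognised by the readers:
#' * optical: `timestamp, rad532, irr532, rad570, irr570, pyr_Wm2, precip_mm`
#' * WSN: `timestamp, ppfd_above_down, ppfd_above_up, ppfd_below_down,
#'   ppfd_below_up, pyr_down, pyr_up`
#' * flux: `timestamp, nee, ustar, tair, ppfd`
#'
#' The readers only check that the expected columns are present; extra
#' columns pass through untouched.
#'
#' @param path CSV file path.
#' @param data A data frame with a `timestamp` column.
#' @name logger_csv
NULL

read_logger_csv <- function(path, required) {
  out <- readr::read_csv(
    path,
    col_types = readr::cols(
      timestamp = readr::col_datetime(),
      .default = readr::col_double()
    ),
    progress = FALSE
  )
  miss <- setdiff(required, names(out))
  if (length(miss) > 0) {
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  out
}

#' @rdname logger_csv
#' @export
read_srs_csv <- function(path) {
  read_logger_csv(path, c("timestamp", "rad532", "irr532", "rad570", "irr570"))
}

#' @rdname logger_csv
#' @export
read_wsn_csv <- function(path) {
  read_logger_csv(path, c("timestamp", "ppfd_above_down", "ppfd_above_up",
                          "ppfd_below_down", "ppfd_below_up",
                          "pyr_down", "pyr_up"))
}

#' @rdname logger_csv
#' @export
read_flux_csv <- function(path) {
  read_logger_csv(path, c("timestamp", "nee", "ustar", "tair", "ppfd"))
}

#' @rdname logger_csv
#' @export
write_logger_csv <- function(data, path) {
  stopifnot("timestamp" %in% names(data))
  out <- dplyr::mutate(
    data,
    timestamp = format(.data$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  )
  readr::write_csv(out, path, na = "")
  invisible(data)
}
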