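#' Light use efficiency
#'
#' `LUE = GPP / APAR`, carbon fixed per unit absorbed photosynthetic
#' radiation (mol CO2 per mol photons when GPP and APAR share micro-mol
#' m-2 s-1 units). Below an APAR floor the ratio is numerically unstable
#' (dawn/dusk) and the value is returned as missing.
#'
#' @param gpp GPP, micro-mol m-2 s-1.
#' @param apar Absorbed PAR (`fAPAR * PPFD`), micro-mol m-2 s-1.
#' @param apar_floor APAR below this is flagged missing.
#'
#' @return LUE series; `NA` below the floor.
#' @examples
#' lue(c(10, 0, 1), c(500, 500, 10))
#' @export
lue <- function(gpp, apar, apar_floor = 50) {
  out <- gpp / apar
  out[is.na(apar) | apar < apar_floor] <- NA_real_
  out
}

#' Proxy-driven light-use-efficiency model
#'
#' Calibrates a linear mapping `LUE = a * proxy + b` from an efficiency
#' proxy (scaled PRI or apparent quantum yield) to LUE by least squares,
#' optionally on a phenological-stage subset. The fitted model predicts
#' GPP as `(a * proxy + b) * APAR` via [predict_gpp()].
#'
#' @param data A data frame with the proxy column, a `lue` column, and
#'   (when `scope != "season"`) a `stage` column.
#' @param proxy Name of the proxy column (string), e.g. `"spri"` or
#'   `"alpha"`.
#' @param scope Training scope: `"season"` (default), `"maturity"` or
#'   `"senescence"`.
#'
#' @return A `lue_model` object with `slope`, `intercept`, `r2`, `p_value`,
#'   `n`, `proxy`, `scope`; `tidy()`/`glance()` methods available.
#' @export
fit_lue_model <- function(data, proxy = "spri", scope = "season") {
  stopifnot(proxy %in% names(data), "lue" %in% names(data))
  if (scope != "season") {
    stopifnot("stage" %in% names(data))
    data <- data[!is.na(data$stage) & data$stage == scope, , drop = FALSE]
  }
  x <- data[[proxy]]
  y <- data$lue
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 10) stop("need at least 10 co-registered records", call. = FALSE)
  if (stats::sd(x[ok]) < 1e-12) {
    stop("degenerate proxy (no variance)", call. = FALSE)
  }
  fit <- stats::lm(y[ok] ~ x[ok])
  sm <- summary(fit)
  structure(
    list(
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      r2 = sm$r.squared,
      p_value = unname(sm$coefficients[2, 4]),
      n = sum(ok),
      proxy = proxy,
      scope = scope
    ),
    class = "lue_model"
  )
}

#' @export
print.lue_model <- function(x, ...) {
  cat(sprintf(
    "<lue_model> LUE = %.4g * %s %+.4g  (scope %s, R2 = %.3f, n = %d)\n",
    x$slope, x$proxy, x$intercept, x$scope, x$r2, x$n
  ))
  invisible(x)
}

#' @rdname fit_lue_model
#' @param x A `lue_model`.
#' @param ... Unused.
#' @export
tidy.lue_model <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", x$proxy),
    estimate = c(x$intercept, x$slope)
  )
}

#' @rdname fit_lue_model
#' @export
glance.lue_model <- function(x, ...) {
  tibble::tibble(r.squared = x$r2, p.value = x$p_value, nobs = x$n,
                 proxy = x$proxy, scope = x$scope)
}

#' Predict GPP from a proxy-driven LUE model
#'
#' `GPP_model = (a * proxy + b) * APAR`. Negative predictions (possible at
#' proxy values below the calibration range) are clipped to zero, so the
#' identity `GPP_model / APAR = modeled LUE` holds wherever nothing was
#' clipped.
#'
#' @param model A `lue_model` from [fit_lue_model()].
#' @param proxy Proxy series.
#' @param apar APAR series, micro-mol m-2 s-1.
#'
#' @return Predicted GPP series, micro-mol m-2 s-1.
#' @export
predict_gpp <- function(model, proxy, apar) {
  stopifnot(inherits(model, "lue_model"))
  pmax((model$slope * proxy + model$intercept) * apar, 0)
}

#' Stage-stratified Pearson correlations
#'
#' Computes the squared Pearson correlation, its two-sided p value, and the
#' sample size between two series over the whole season and within each
#' phenological stage -- the analysis used to separate facultative
#' (xanthophyll-driven) from constitutive (structure-driven) components of
#' the PRI signal.
#'
#' @param data A data frame holding both series and a `stage` column with
#'   values `maturity`/`senescence`.
#' @param x,y Column names (strings) of the two series.
#' @param min_n Scopes with fewer complete pairs than this are omitted.
#'
#' @return A tibble with columns `x`, `y`, `scope`, `r2`, `p_value`, `n`.
#' @export
stratified_correlation <- function(data, x, y, min_n = 3) {
  stopifnot(x %in% names(data), y %in% names(data), "stage" %in% names(data))
  scopes <- list(
    season = rep(TRUE, nrow(data)),
    maturity = !is.na(data$stage) & data$stage == "maturity",
    senescence = !is.na(data$stage) & data$stage == "senescence"
  )
  purrr::imap(scopes, function(sel, name) {
    xv <- data[[x]][sel]
    yv <- data[[y]][sel]
    ok <- is.finite(xv) & is.finite(yv)
    if (sum(ok) < min_n) return(NULL)
    if (stats::sd(xv[ok]) < 1e-12 || stats::sd(yv[ok]) < 1e-12) return(NULL)
    ct <- stats::cor.test(xv[ok], yv[ok])
    tibble::tibble(
      x = x, y = y, scope = name,
      r2 = unname(ct$estimate)^2,
      p_value = ct$p.value,
      n = sum(ok)
    )
  }) |>
    purrr::compact() |>
    dplyr::bind_rows()
}
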