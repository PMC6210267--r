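#' Eddy-covariance NEE from vertical wind and mixing-ratio series
#'
#' Demonstration-grade block covariance: net ecosystem exchange is the
#' product of mean dry-air density and the covariance of instantaneous
#' vertical wind velocity and CO2 molar mixing-ratio fluctuations,
#' `NEE = -rho_a * cov(w', s')`, with the meteorological sign convention
#' (negative NEE = net uptake). High-frequency corrections (despiking,
#' coordinate rotation, WPL, spectral corrections) are out of scope; field
#' pipelines consume finished 30-min fluxes.
#'
#' @param w Vertical wind velocity series, m s-1.
#' @param s CO2 molar mixing ratio series, mol mol-1 dry air.
#' @param rho_a Mean dry-air density over the block, mol m-3.
#'
#' @return NEE in mol m-2 s-1 times the units of `s` (with `s` in
#'   micro-mol/mol the result is micro-mol m-2 s-1).
#' @examples
#' covariance_nee(c(0.1, -0.1), c(4e-4, 4e-4), 40) # s constant -> 0
#' @export
covariance_nee <- function(w, s, rho_a) {
  if (length(w) != length(s)) {
    stop("`w` and `s` must have equal length", call. = FALSE)
  }
  if (length(w) < 2) stop("block length must be >= 2", call. = FALSE)
  -rho_a * mean((w - mean(w)) * (s - mean(s)))
}

#' Friction-velocity filter
#'
#' Flags 30-min records measured under poor turbulent mixing, identified by
#' friction velocity strictly below the threshold (`u* < threshold`
#' removed, so a record exactly at the threshold is retained).
#'
#' @param data Flux records with a `ustar` column, m s-1.
#' @param threshold u* threshold, m s-1 (default 0.21).
#'
#' @return `data` with a logical `ustar_flag` column; `TRUE` marks removal.
#' @export
ustar_filter <- function(data, threshold = 0.21) {
  stopifnot(threshold > 0, "ustar" %in% names(data))
  dplyr::mutate(data, ustar_flag = !is.na(.data$ustar) & .data$ustar < threshold)
}

# Gauss-Newton with step halving on a residual/Jacobian pair.
# fn(theta) must return list(resid =, jac =). Returns list(theta, converged,
# rss, iters).
gauss_newton <- function(fn, theta0, max_iter = 100, tol = 1e-10) {
  theta <- theta0
  r <- fn(theta)
  rss <- sum(r$resid^2)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    J <- r$jac
    g <- crossprod(J, r$resid)
    H <- crossprod(J)
    step <- tryCatch(
      drop(solve(H + diag(1e-10 * max(diag(H), 1e-12), ncol(H)), g)),
      error = function(e) NULL
    )
    if (is.null(step) || any(!is.finite(step))) break
    lambda <- 1
    improved <- FALSE
    for (h in 1:30) { # step halving
      cand <- theta - lambda * step
      rc <- tryCatch(fn(cand), error = function(e) NULL)
      if (!is.null(rc) && all(is.finite(rc$resid))) {
        rss_c <- sum(rc$resid^2)
        if (rss_c <= rss) {
          theta <- cand
          r <- rc
          improved <- TRUE
          if ((rss - rss_c) <= tol * (rss + tol)) {
            converged <- TRUE
          }
          rss <- rss_c
          break
        }
      }
      lambda <- lambda / 2
    }
    if (!improved) {
      converged <- TRUE # stuck at a (local) optimum
      break
    }
    if (converged) break
  }
  list(theta = theta, converged = converged, rss = rss, iters = it)
}

# respiration model R10 * Q10^((T-10)/10)
reco_model <- function(tair, r10, q10) {
  r10 * q10^((tair - 10) / 10)
}

#' Nighttime respiration regression
#'
#' Fits the temperature-response respiration model
#' `NEE_night = R10 * Q10^((Tair - 10) / 10)` to nighttime (PPFD below
#' `night_ppfd`), u*-screened records by least squares, and extrapolates
#' ecosystem respiration to all records with the fitted parameters. This is
#' a deliberately simplified partitioning: one window, one (R10, Q10) pair,
#' reusing the same respiration term as the light-response model.
#'
#' @param data Flux records with `nee`, `tair`, `ppfd` columns (and
#'   optionally `ustar_flag` from [ustar_filter()], honoured if present).
#' @param night_ppfd PPFD threshold defining night, micro-mol m-2 s-1.
#' @param min_night Minimum number of usable nighttime records.
#'
#' @return A list with `r10`, `q10`, `converged`, `n_night`, and `reco`, the
#'   respiration series evaluated at every row of `data`.
#' @export
nighttime_reco <- function(data, night_ppfd = 5, min_night = 30) {
  stopifnot(all(c("nee", "tair", "ppfd") %in% names(data)))
  keep <- !is.na(data$nee) & !is.na(data$tair) & !is.na(data$ppfd) &
    data$ppfd < night_ppfd
  if ("ustar_flag" %in% names(data)) keep <- keep & !data$ustar_flag
  night <- data[keep, , drop = FALSE]
  if (nrow(night) < min_night) {
    stop(sprintf("only %d usable nighttime records (need >= %d)",
                 nrow(night), min_night), call. = FALSE)
  }
  if (stats::sd(night$tair) < 0.5) {
    return(list(r10 = mean(pmax(night$nee, 0)), q10 = NA_real_,
                converged = FALSE, n_night = nrow(night),
                reco = rep(mean(pmax(night$nee, 0)), nrow(data))))
  }
  # log-linear initial values where respiration is positive
  pos <- night$nee > 0
  init <- if (sum(pos) >= 10) {
    lf <- stats::lm(log(nee) ~ I((tair - 10) / 10), data = night[pos, ])
    c(exp(stats::coef(lf)[[1]]), exp(stats::coef(lf)[[2]]))
  } else {
    c(max(mean(night$nee), 0.1), 2)
  }
  init[1] <- max(init[1], 1e-3)
  init[2] <- min(max(init[2], 1.05), 4)

  fn <- function(th) {
    r10 <- th[1]; q10 <- th[2]
    u <- (night$tair - 10) / 10
    pred <- r10 * q10^u
    list(
      resid = pred - night$nee,
      jac = cbind(q10^u, r10 * u * q10^(u - 1))
    )
  }
  fit <- gauss_newton(fn, init)
  r10 <- fit$theta[1]; q10 <- fit$theta[2]
  list(
    r10 = r10, q10 = q10, converged = fit$converged, n_night = nrow(night),
    reco = reco_model(data$tair, r10, q10)
  )
}

#' Bin flux records into composite 2-day diurnal cycles
#'
#' Averages NEE, PPFD and Tair by time-of-day within consecutive 2-day
#' blocks, producing one representative diurnal pattern per block --
#' the input the light-response fit expects. Records flagged by
#' [ustar_filter()] are excluded from the averages.
#'
#' @param data 30-min flux records with `timestamp`, `nee`, `ppfd`, `tair`
#'   (and optionally `ustar_flag`).
#'
#' @return A tibble with `window` (first date of the 2-day block), `tod_min`
#'   (minutes since local midnight of the timestamp grid), and binned
#'   `nee`, `ppfd`, `tair`.
#' @export
bin_two_day <- function(data) {
  stopifnot(all(c("timestamp", "nee", "ppfd", "tair") %in% names(data)))
  if ("ustar_flag" %in% names(data)) {
    data <- dplyr::filter(data, !.data$ustar_flag)
  }
  d0 <- min(lubridate::as_date(data$timestamp))
  data |>
    dplyr::mutate(
      window = d0 + 2 * (as.numeric(lubridate::as_date(.data$timestamp) - d0) %/% 2),
      tod_min = lubridate::hour(.data$timestamp) * 60 +
        lubridate::minute(.data$timestamp)
    ) |>
    dplyr::group_by(.data$window, .data$tod_min) |>
    dplyr::summarise(
      nee = mean(.data$nee, na.rm = TRUE),
      ppfd = mean(.data$ppfd, na.rm = TRUE),
      tair = mean(.data$tair, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::filter(is.finite(.data$nee), is.finite(.data$ppfd),
                  is.finite(.data$tair))
}

#' Rectangular-hyperbola light-response fit
#'
#' Fits the light-response model
#'
#'   NEE = -(Amax * alpha * PPFD) / (Amax + alpha * PPFD)
#'         + R10 * Q10^((Tair - 10) / 10)
#'
#' to a composite diurnal cycle by nonlinear least squares (Gauss-Newton
#' with step halving and an analytic Jacobian; optional
#' Levenberg-Marquardt fallback through minpack.lm when Gauss-Newton fails
#' to converge). `Amax` is the assimilation asymptote at saturating PPFD
#' (micro-mol m-2 s-1), `alpha` the apparent quantum yield -- the initial
#' slope of the light response (mol CO2 per mol photons) -- and
#' `R10`/`Q10` the base respiration at 10 C and its temperature
#' sensitivity. Parameter sanity bounds (`alpha <= 0.125`, the theoretical
#' quantum-yield ceiling; `Q10` in \[1, 4\]) are checked after fitting and
#' reported as a flag, never enforced by clipping.
#'
#' @param data A single composite window: `nee`, `ppfd`, `tair` columns
#'   (typically one `window` of [bin_two_day()]).
#' @param init Optional named initial values (`amax`, `alpha`, `r10`,
#'   `q10`). Defaults: `amax` = 95th percentile of -NEE, `alpha` = 0.02,
#'   `r10` = mean nighttime NEE, `q10` = 2.
#'
#' @return A `light_response` object: list with `amax`, `alpha`, `r10`,
#'   `q10`, `converged`, `within_bounds`, `alpha_se` (linearised standard
#'   error of `alpha` from the Jacobian at the optimum), `reliable`
#'   (converged, within bounds, and `alpha` resolved at better than 50%
#'   relative standard error -- windows with no appreciable assimilation
#'   signal, e.g. deep senescence, fail this), `rss`, `n`, plus `gpp`, the
#'   fitted hyperbola `(Amax alpha PPFD) / (Amax + alpha PPFD)` evaluated
#'   at the input PPFD. `tidy()`/`glance()` methods available.
#' @export
light_response_fit <- function(data, init = NULL) {
  stopifnot(all(c("nee", "ppfd", "tair") %in% names(data)))
  d <- data[is.finite(data$nee) & is.finite(data$ppfd) & is.finite(data$tair), ]
  n <- nrow(d)
  fail <- function() {
    structure(list(amax = NA_real_, alpha = NA_real_, r10 = NA_real_,
                   q10 = NA_real_, converged = FALSE, within_bounds = FALSE,
                   alpha_se = NA_real_, reliable = FALSE,
                   rss = NA_real_, n = n, gpp = rep(NA_real_, nrow(data))),
              class = "light_response")
  }
  if (n < 10) return(fail())
  # identifiability guards: need light variation and some lit records
  if (stats::sd(d$ppfd) < 1 || max(d$ppfd) < 50) return(fail())

  if (is.null(init)) {
    night <- d$nee[d$ppfd < 5]
    init <- c(
      amax = max(stats::quantile(-d$nee, 0.95, names = FALSE), 1),
      alpha = 0.02,
      r10 = max(if (length(night) > 0) mean(night) else 1, 0.1),
      q10 = 2
    )
  }
  fn <- function(th) {
    amax <- th[1]; alpha <- th[2]; r10 <- th[3]; q10 <- th[4]
    if (amax <= 0 || alpha <= 0 || q10 <= 0) stop("out of domain")
    q <- d$ppfd
    u <- (d$tair - 10) / 10
    den <- amax + alpha * q
    pred <- -(amax * alpha * q) / den + r10 * q10^u
    list(
      resid = pred - d$nee,
      jac = cbind(
        -(alpha * q)^2 / den^2,   # d/dAmax
        -amax^2 * q / den^2,      # d/dalpha
        q10^u,                    # d/dR10
        r10 * u * q10^(u - 1)     # d/dQ10
      )
    )
  }
  fit <- gauss_newton(fn, init)
  th <- fit$theta
  converged <- fit$converged && all(is.finite(th))

  if (!converged && requireNamespace("minpack.lm", quietly = TRUE)) {
    lm_fit <- tryCatch(
      minpack.lm::nlsLM(
        nee ~ -(amax * alpha * ppfd) / (amax + alpha * ppfd) +
          r10 * q10^((tair - 10) / 10),
        data = d, start = as.list(init),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (!is.null(lm_fit)) {
      th <- stats::coef(lm_fit)[c("amax", "alpha", "r10", "q10")]
      fit$rss <- sum(stats::resid(lm_fit)^2)
      converged <- TRUE
    }
  }
  if (!converged) return(fail())

  amax <- th[[1]]; alpha <- th[[2]]; r10 <- th[[3]]; q10 <- th[[4]]
  # sanity bounds: alpha capped at the theoretical quantum-yield ceiling,
  # amax at a generous canopy physiological ceiling (a runaway amax means
  # the hyperbola degenerated to a straight line), and the half-saturation
  # PPFD amax/alpha at 100 umol m-2 s-1 (real light responses
  # half-saturate far above that; smaller ratios are the degenerate
  # flat-data corner where the curve saturates within the noise)
  within <- amax > 0 && amax <= 100 && alpha > 0 && alpha <= 0.125 &&
    amax / alpha >= 100 && r10 >= 0 && q10 >= 1 && q10 <= 4

  # linearised standard error of alpha at the optimum
  alpha_se <- NA_real_
  jac <- tryCatch(fn(c(amax, alpha, r10, q10))$jac, error = function(e) NULL)
  if (!is.null(jac) && n > 4) {
    sigma2 <- fit$rss / (n - 4)
    covm <- tryCatch(sigma2 * solve(crossprod(jac)), error = function(e) NULL)
    if (!is.null(covm) && is.finite(covm[2, 2]) && covm[2, 2] >= 0) {
      alpha_se <- sqrt(covm[2, 2])
    }
  }
  reliable <- within && is.finite(alpha_se) && alpha_se < 0.5 * abs(alpha)

  gpp <- (amax * alpha * data$ppfd) / (amax + alpha * data$ppfd)
  structure(
    list(amax = amax, alpha = alpha, r10 = r10, q10 = q10,
         converged = TRUE, within_bounds = within,
         alpha_se = alpha_se, reliable = reliable, rss = fit$rss, n = n,
         gpp = gpp),
    class = "light_response"
  )
}

#' @export
print.light_response <- function(x, ...) {
  if (!x$converged) {
    cat("<light_response> fit did not converge\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<light_response> Amax %.2f, alpha %.4f, R10 %.2f, Q10 %.2f (n %d, rss %.2f%s)\n",
    x$amax, x$alpha, x$r10, x$q10, x$n, x$rss,
    if (x$within_bounds) "" else ", OUT OF BOUNDS"
  ))
  invisible(x)
}

#' @rdname light_response_fit
#' @param x A `light_response` object.
#' @param ... Unused.
#' @export
tidy.light_response <- function(x, ...) {
  tibble::tibble(
    term = c("amax", "alpha", "r10", "q10"),
    estimate = c(x$amax, x$alpha, x$r10, x$q10)
  )
}

#' @rdname light_response_fit
#' @export
glance.light_response <- function(x, ...) {
  tibble::tibble(converged = x$converged, within_bounds = x$within_bounds,
                 rss = x$rss, nobs = x$n)
}

#' Light-response parameters for every 2-day window of a season
#'
#' Runs [light_response_fit()] on each consecutive 2-day window of the
#' record, returning the seasonal trajectory of `Amax`, apparent quantum
#' yield `alpha`, and the respiration parameters. By default each window's
#' raw half-hourly records are fitted directly (`composite = FALSE`):
#' averaging NEE by time-of-day across days ([bin_two_day()]) mixes
#' different sky conditions at the same clock time, which biases a curved
#' light response (the mean of the hyperbola is not the hyperbola of the
#' mean) and discards the within-day PPFD leverage that identifies
#' `alpha`. The composite-diurnal variant remains available.
#' Windows whose fit does not converge or falls outside the parameter
#' sanity bounds are flagged.
#'
#' @param data 30-min flux records (`timestamp`, `nee`, `ppfd`, `tair`,
#'   optional `ustar_flag`).
#' @param composite If `TRUE`, fit the 2-day composite diurnal cycle
#'   instead of the raw records.
#'
#' @return A tibble with one row per 2-day window: `window`, `amax`,
#'   `alpha`, `r10`, `q10`, `alpha_se`, `converged`, `within_bounds`,
#'   `reliable`, `n`.
#' @export
fit_light_response_windows <- function(data, composite = FALSE) {
  if (composite) {
    binned <- bin_two_day(data)
  } else {
    stopifnot(all(c("timestamp", "nee", "ppfd", "tair") %in% names(data)))
    if ("ustar_flag" %in% names(data)) {
      data <- dplyr::filter(data, !.data$ustar_flag)
    }
    d0 <- min(lubridate::as_date(data$timestamp))
    binned <- dplyr::mutate(
      data,
      window = d0 +
        2 * (as.numeric(lubridate::as_date(.data$timestamp) - d0) %/% 2)
    )
  }
  binned |>
    dplyr::group_by(.data$window) |>
    dplyr::group_modify(function(d, key) {
      f <- light_response_fit(d)
      tibble::tibble(
        amax = f$amax, alpha = f$alpha, r10 = f$r10, q10 = f$q10,
        alpha_se = f$alpha_se, converged = f$converged,
        within_bounds = f$within_bounds, reliable = f$reliable, n = f$n
      )
    }) |>
    dplyr::ungroup()
}

#' Partition NEE into GPP given a respiration series
#'
#' Under the meteorological sign convention `NEE = -GPP + Reco`, so
#' `GPP = Reco - NEE`. Negative partitioned GPP (possible under noise) is
#' clipped to zero and flagged.
#'
#' @param nee NEE series, micro-mol m-2 s-1 (negative = uptake).
#' @param reco Ecosystem respiration series, micro-mol m-2 s-1 (>= 0).
#'
#' @return A tibble with `gpp` and logical `gpp_clipped`.
#' @examples
#' partition_gpp(c(-8, 2, 3), c(2, 2, 1))
#' @export
partition_gpp <- function(nee, reco) {
  stopifnot(all(reco >= 0, na.rm = TRUE))
  gpp <- reco - nee
  clipped <- !is.na(gpp) & gpp < 0
  gpp[clipped] <- 0
  tibble::tibble(gpp = gpp, gpp_clipped = clipped)
}
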