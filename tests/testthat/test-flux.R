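test_that("covariance NEE follows the flux algebra and sign convention", {
  # constructed block with population covariance exactly 0.25 (umol/mol m/s)
  w <- c(-1, 1)
  s <- c(-0.25, 0.25) + 400
  expect_equal(covariance_nee(w, s, 40), -10)
  # constant mixing ratio: exactly zero
  expect_identical(covariance_nee(c(0.3, -0.2, 0.1), rep(400, 3), 40), 0)
  # uncorrelated series: near zero relative to the marginal scales
  set.seed(5)
  wn <- rnorm(20000, 0, 0.3)
  sn <- rnorm(20000, 400, 10)
  expect_lt(abs(covariance_nee(wn, sn, 40)), 5 * 40 * 0.3 * 10 / sqrt(20000))
  expect_error(covariance_nee(1:3, 1:4, 40), "equal length")
  expect_error(covariance_nee(1, 1, 40), "length")
})

test_that("the u* filter removes strictly-below-threshold records", {
  d <- tibble::tibble(ustar = c(0.20, 0.21, 0.35, NA))
  out <- ustar_filter(d)
  expect_identical(out$ustar_flag, c(TRUE, FALSE, FALSE, FALSE))
  # all above threshold: identity
  expect_false(any(ustar_filter(tibble::tibble(ustar = c(0.3, 0.5)))$ustar_flag))
})

test_that("nighttime respiration regression inverts its own model", {
  mk_night <- function(n, r10, q10, sd = 0) {
    tair <- runif(n, 0, 20)
    tibble::tibble(
      nee = r10 * q10^((tair - 10) / 10) + rnorm(n, 0, sd),
      tair = tair, ppfd = 0
    )
  }
  set.seed(21)
  # noiseless: exact within solver tolerance, and the extrapolated series
  # equals the model at every record's temperature
  night0 <- mk_night(60, 2, 2)
  fit0 <- nighttime_reco(night0)
  expect_equal(fit0$r10, 2, tolerance = 1e-6)
  expect_equal(fit0$q10, 2, tolerance = 1e-6)
  expect_true(fit0$converged)
  expect_equal(fit0$reco, 2 * 2^((night0$tair - 10) / 10), tolerance = 1e-5)

  # noisy: both parameters within 10%
  set.seed(22)
  fit1 <- nighttime_reco(mk_night(200, 2, 2, sd = 0.5))
  expect_lt(abs(fit1$r10 - 2) / 2, 0.1)
  expect_lt(abs(fit1$q10 - 2) / 2, 0.1)

  # isothermal nights: Q10 unidentifiable, flagged
  iso <- tibble::tibble(nee = rnorm(50, 2, 0.1), tair = 10.1, ppfd = 0)
  fit2 <- nighttime_reco(iso)
  expect_false(fit2$converged)
  expect_true(is.na(fit2$q10))

  expect_error(nighttime_reco(mk_night(10, 2, 2)), "nighttime records")
})

test_that("the light-response fit inverts noiseless data to 1e-4 relative", {
  d <- make_lr_window(amax = 20, alpha = 0.03, r10 = 2, q10 = 2)
  f <- light_response_fit(d)
  expect_true(f$converged)
  expect_true(f$within_bounds)
  expect_lt(abs(f$amax - 20) / 20, 1e-4)
  expect_lt(abs(f$alpha - 0.03) / 0.03, 1e-4)
  expect_lt(abs(f$r10 - 2) / 2, 1e-4)
  expect_lt(abs(f$q10 - 2) / 2, 1e-4)
  expect_equal(tidy(f)$estimate[2], f$alpha)
  expect_true(glance(f)$converged)
})

test_that("median alpha error stays below 5% at 0.5 umol noise", {
  errs <- vapply(1:100, function(i) {
    set.seed(i)
    f <- light_response_fit(make_lr_window(noise = 0.5))
    if (f$converged) abs(f$alpha - 0.03) / 0.03 else NA_real_
  }, numeric(1))
  expect_gt(sum(!is.na(errs)), 95)
  expect_lt(median(errs, na.rm = TRUE), 0.05)
})

test_that("the fitter agrees with a brute-force grid search", {
  for (i in 1:3) {
    set.seed(100 + i)
    truth <- c(amax = runif(1, 12, 30), alpha = runif(1, 0.015, 0.05))
    d <- make_lr_window(truth["amax"], truth["alpha"], noise = 0.5)
    f <- light_response_fit(d)
    g <- grid_oracle_lr(d)
    # same optimum within the refined grid resolution
    expect_lt(abs(f$amax - g$par["amax"]) / g$par["amax"], 0.05)
    expect_lt(abs(f$alpha - g$par["alpha"]) / g$par["alpha"], 0.05)
    expect_lte(f$rss, g$sse * (1 + 1e-3))
  }
})

test_that("the fitter matches an independent nls implementation", {
  set.seed(42)
  d <- make_lr_window(noise = 0.3)
  f <- light_response_fit(d)
  ref <- stats::nls(
    nee ~ -(amax * alpha * ppfd) / (amax + alpha * ppfd) +
      r10 * q10^((tair - 10) / 10),
    data = d,
    start = list(amax = 15, alpha = 0.02, r10 = 1.5, q10 = 1.8)
  )
  expect_equal(f$alpha, stats::coef(ref)[["alpha"]], tolerance = 1e-4)
  expect_equal(f$amax, stats::coef(ref)[["amax"]], tolerance = 1e-4)
})

test_that("degenerate windows are flagged, not fitted", {
  # PPFD identically zero: assimilation parameters unidentifiable
  dark <- make_lr_window()
  dark$ppfd <- 0
  f <- light_response_fit(dark)
  expect_false(f$converged)
  expect_true(is.na(f$alpha))
  # too few records
  expect_false(light_response_fit(make_lr_window()[1:5, ])$converged)
})

test_that("fitted GPP is monotone and saturates at Amax", {
  d <- make_lr_window(amax = 18, alpha = 0.025)
  f <- light_response_fit(d)
  q <- sort(unique(d$ppfd))
  gpp <- (f$amax * f$alpha * q) / (f$amax + f$alpha * q)
  expect_true(all(diff(gpp) > -1e-12))
  expect_lt(max(gpp), f$amax)
  huge <- (f$amax * f$alpha * 1e7) / (f$amax + f$alpha * 1e7)
  expect_equal(huge, f$amax, tolerance = 1e-3)
})

test_that("two-day composite binning averages by time of day", {
  base <- as.POSIXct("2015-07-01 00:00:00", tz = "UTC")
  d <- tibble::tibble(
    timestamp = base + 1800 * (0:191), # 4 days of half-hours
    nee = rep(c(1, 3), each = 96)[1:192] + rep(0:47, 4) * 0,
    ppfd = 500, tair = 15
  )
  out <- bin_two_day(d)
  expect_equal(sort(unique(out$window)),
               as.Date(c("2015-07-01", "2015-07-03")))
  expect_true(all(out$nee[out$window == as.Date("2015-07-01")] == 1))
  expect_true(all(out$nee[out$window == as.Date("2015-07-03")] == 3))
  expect_equal(nrow(out), 96)
})

test_that("per-window fits recover distinct quantum yields", {
  set.seed(8)
  base <- as.POSIXct("2015-07-01 00:00:00", tz = "UTC")
  w1 <- make_lr_window(alpha = 0.03, noise = 0.3)
  w2 <- make_lr_window(alpha = 0.015, noise = 0.3)
  d <- dplyr::bind_rows(w1, w2)
  d$timestamp <- base + 1800 * (seq_len(nrow(d)) - 1)
  out <- fit_light_response_windows(d)
  expect_equal(nrow(out), 2)
  expect_equal(out$alpha, c(0.03, 0.015), tolerance = 0.15)
  expect_true(all(out$converged))
})

test_that("GPP partitioning respects the sign convention and clips", {
  out <- partition_gpp(c(-8, 2, 3), c(2, 2, 1))
  expect_equal(out$gpp, c(10, 0, 0))
  expect_identical(out$gpp_clipped, c(FALSE, FALSE, TRUE))
  expect_error(partition_gpp(-5, -1), "reco")
})
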