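test_that("the ideal diffuse-reflector ratio is 1/pi", {
  expect_equal(lambertian_ratio(), 1 / pi)
  expect_equal(round(lambertian_ratio(), 3), 0.318)
  expect_equal(lambertian_ratio(0.99), 0.99 / pi)
  expect_error(lambertian_ratio(0), "panel_reflectance")
})

make_panel_grid <- function(ratio_fun, elevations = seq(1, 50, by = 0.5),
                            illums = seq(20, 100, by = 2)) {
  g <- expand.grid(elevation_deg = elevations, illumination_pct = illums)
  tibble::tibble(
    timestamp = as.POSIXct("2015-06-15", tz = "UTC") + seq_len(nrow(g)),
    band = 532,
    i_sky = 1,
    r_standard = ratio_fun(g$elevation_deg, g$illumination_pct),
    illumination_pct = g$illumination_pct,
    elevation_deg = g$elevation_deg
  )
}

test_that("a constant panel ratio yields flat calibration functions", {
  panel <- make_panel_grid(function(el, il) rep(0.318, length(el)))
  cal <- suppressWarnings(fit_calibration(panel, aspen_site())) # exact fit
  expect_true(all(abs(cal$slope) < 1e-6))
  expect_true(all(abs(cal$intercept - 0.318) < 1e-6))
  expect_true(all(cal$r2 >= 0 | is.nan(cal$r2)))
})

test_that("a linear illumination bias is recovered within sampling error", {
  # single bin [39, 42): ratio = 0.35 - 0.0004 * illum + noise
  fit_one <- function(n, sd) {
    illum <- runif(n, 15, 100)
    tibble::tibble(
      timestamp = as.POSIXct("2015-06-15", tz = "UTC") + seq_len(n),
      band = 532, i_sky = 1,
      r_standard = 0.35 - 4e-4 * illum + rnorm(n, 0, sd),
      illumination_pct = illum,
      elevation_deg = runif(n, 39, 42)
    ) |>
      fit_calibration(aspen_site())
  }
  set.seed(11)
  cal <- fit_one(200, 0.005)
  # analytic OLS slope standard error at this design
  se_slope <- 0.005 / (sqrt(200) * sqrt((100 - 15)^2 / 12))
  expect_lt(abs(cal$slope - (-4e-4)), 3 * se_slope)
  expect_lt(abs(cal$intercept - 0.35) / 0.35, 0.02)

  # with generous n the 2% relative recovery holds for both coefficients
  cal2 <- fit_one(5000, 0.005)
  expect_lt(abs(cal2$slope - (-4e-4)) / 4e-4, 0.02)
  expect_lt(abs(cal2$intercept - 0.35) / 0.35, 0.02)
})

test_that("degenerate and undersized bins are omitted, empty input rejected", {
  site <- aspen_site()
  expect_error(fit_calibration(tibble::tibble(), site), "columns")
  base <- tibble::tibble(
    timestamp = as.POSIXct("2015-06-15", tz = "UTC") + 1:30,
    band = 532, i_sky = 1, r_standard = 0.3,
    illumination_pct = 50, elevation_deg = 40
  )
  # constant illumination -> degenerate spread -> bin omitted -> no bins
  expect_error(expect_warning(fit_calibration(base, site), "degenerate"),
               "minimum-n")
  # too few points in a second bin: silently dropped
  panel <- make_panel_grid(function(el, il) 0.3 + il * 0)
  panel2 <- dplyr::bind_rows(
    panel,
    dplyr::mutate(panel[1:3, ], elevation_deg = 55)
  )
  cal <- suppressWarnings(fit_calibration(panel2, site)) # exact-fit warnings
  expect_false(18L %in% cal$bin)
})

test_that("campaign-fitted functions show the expected elevation structure", {
  cfg <- generator_config(seed = 42)
  camp <- generate_panel_campaign(cfg)
  cal <- fit_calibration(camp$panel, aspen_site())

  # slopes negative (higher ratios under diffuse light) and steeper at
  # low elevations than near noon
  expect_true(all(cal$slope < 0))
  low <- cal$slope[cal$bin <= 5]
  high <- cal$slope[cal$bin >= 15]
  expect_lt(mean(low), mean(high))

  # intercepts scatter around the Lambertian panel ratio
  expect_true(all(abs(cal$intercept - lambertian_ratio(0.99)) < 0.15))

  # per-bin ratio spread decreases with elevation (specular noise model)
  spread <- camp$panel |>
    dplyr::filter(band == 532, illumination_pct >= 15) |>
    dplyr::mutate(bin = elevation_bin(elevation_deg),
                  ratio = r_standard / i_sky) |>
    dplyr::group_by(bin) |>
    dplyr::summarise(s = sd(ratio), n = dplyr::n()) |>
    dplyr::filter(n >= 100)
  fit <- stats::lm(s ~ bin, data = spread)
  expect_lt(stats::coef(fit)[["bin"]], 0)
})

test_that("correction ratios follow the fitted line with clamping and fallback", {
  cal <- make_calset(tibble::tibble(
    band = c(532, 532), bin = c(10, 13),
    slope = c(-4e-4, 0), intercept = c(0.35, 0.318)
  ))
  # slope 0: constant
  r0 <- correction_ratio(cal, 532, 41, 70, "diurnal")
  expect_equal(r0$ratio, 0.318)
  # arithmetic on the linear function
  r1 <- correction_ratio(cal, 532, 31, 50, "diurnal")
  expect_equal(r1$ratio, 0.33)
  expect_false(r1$fallback)
  expect_false(r1$clamped)
  # illumination beyond the fitted range: capped at 120 then clamped to
  # the bin maximum, flagged
  r2 <- correction_ratio(cal, 532, 31, 140, "diurnal")
  expect_equal(r2$ratio, 0.35 - 4e-4 * 100)
  expect_true(r2$clamped)
  # elevation in an unfitted bin: nearest retained bin, flagged
  r3 <- correction_ratio(cal, 532, 55, 50, "diurnal")
  expect_identical(r3$bin_used, 13L)
  expect_true(r3$fallback)
  # midday mode keys on the noon elevation, not the instantaneous one
  r4 <- correction_ratio(cal, 532, 10, 50, "midday", noon_elevation_deg = 41)
  expect_identical(r4$bin_used, 13L)
  # night elevations yield missing ratios
  r5 <- correction_ratio(cal, 532, -4, 50, "diurnal")
  expect_true(is.na(r5$ratio))
})

test_that("reflectance correction divides by the panel ratio", {
  expect_equal(correct_reflectance(0.0318, 0.318), 0.1)
  expect_equal(correct_reflectance(0.07, 1), 0.07)
  expect_true(is.na(correct_reflectance(0.1, 0)))
  expect_true(is.na(correct_reflectance(0.1, -0.2)))
})

test_that("equal-band ratios preserve PRI; differential ratios shift it", {
  rho532 <- 0.04; rho570 <- 0.05
  p0 <- pri(rho532, rho570)
  expect_equal(pri(correct_reflectance(rho532, 0.3),
                   correct_reflectance(rho570, 0.3)), p0)
  p_shift <- pri(correct_reflectance(rho532, 0.28),
                 correct_reflectance(rho570, 0.33))
  expect_gt(p_shift, p0)
})

test_that("calibration files round-trip through the plain-text format", {
  cfg <- generator_config(seed = 42)
  cal <- fit_calibration(generate_panel_campaign(cfg)$panel, aspen_site())
  path <- withr::local_tempfile(fileext = ".csv")
  write_calibration(cal, path)
  cal2 <- read_calibration(path)
  expect_equal(attr(cal2, "bin_width_deg"), attr(cal, "bin_width_deg"))
  expect_equal(tidy(cal2), tidy(cal), tolerance = 1e-12)
  expect_error(read_calibration(withr::local_tempfile(lines = "x,y")),
               "calibration file")
})

test_that("diurnal correction recovers true canopy reflectance end to end", {
  cfg <- generator_config(
    seed = 42,
    season_start = as.Date("2015-06-15"), season_end = as.Date("2015-06-28")
  )
  cal <- fit_calibration(generate_panel_campaign(cfg)$panel, aspen_site())
  season <- generate_season(cfg)

  opt <- season$optical |>
    filter_precipitation(season$optical[, c("timestamp", "precip_mm")]) |>
    dplyr::filter(!precip_flag) |>
    srs_reflectance()
  corr <- apply_calibration(opt, cal, aspen_site(), "diurnal") |>
    dplyr::select(timestamp, rho532, spri) |>
    bin_halfhour()
  j <- dplyr::inner_join(corr, season$truth, by = "timestamp") |>
    dplyr::filter(elevation_deg >= 10, elevation_deg <= 55,
                  is.finite(rho532))
  rel <- abs(j$rho532 - j$rho532_true) / j$rho532_true
  expect_lt(median(rel), 0.03)

  # uncorrected reflectance is biased by the full fore-optic gain scale
  unc <- bin_halfhour(dplyr::select(opt, timestamp, rho532)) |>
    dplyr::inner_join(season$truth, by = "timestamp") |>
    dplyr::filter(elevation_deg >= 10, is.finite(rho532))
  expect_gt(
    median(abs(unc$rho532 - unc$rho532_true)),
    5 * median(abs(j$rho532 - j$rho532_true))
  )
})
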