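test_that("identical seeds reproduce bit-identical campaigns and seasons", {
  c1 <- generate_panel_campaign(generator_config(seed = 3))
  c2 <- generate_panel_campaign(generator_config(seed = 3))
  expect_identical(c1$panel, c2$panel)
  c3 <- generate_panel_campaign(generator_config(seed = 4))
  expect_false(identical(c1$panel$r_standard, c3$panel$r_standard))

  t1 <- generate_season_truth(generator_config(seed = 3))
  t2 <- generate_season_truth(generator_config(seed = 3))
  expect_identical(t1, t2)
  t3 <- generate_season_truth(generator_config(seed = 4))
  expect_false(identical(t1$alpha_true, t3$alpha_true))
})

test_that("the default campaign spans the documented illumination and elevation ranges", {
  camp <- generate_panel_campaign(generator_config(seed = 1))
  p <- camp$panel
  expect_lte(min(p$illumination_pct, na.rm = TRUE), 15)
  expect_gte(max(p$illumination_pct, na.rm = TRUE), 100)
  expect_lte(min(p$elevation_deg), 5)
  expect_gte(max(p$elevation_deg), 55)
  expect_true(all(p$i_sky > 0))
  # ratios scatter around the Lambertian panel value
  expect_equal(median(p$r_standard / p$i_sky), 0.318, tolerance = 0.05)
})

test_that("the analytic calibration truth matches the gain model", {
  cfg <- generator_config(seed = 1)
  tr <- true_calibration(cfg, bins = c(2, 10), el_deg = c(7.5, 31.5))
  for (i in seq_len(nrow(tr))) {
    for (il in c(20, 60, 100)) {
      expect_equal(
        tr$slope[i] * il + tr$intercept[i],
        priflux:::true_cc_ratio(cfg, tr$band[i], il,
                                c(2, 10, 2, 10)[i] * 3 + 1.5),
        tolerance = 1e-12
      )
    }
  }
})

test_that("generated physical fractions stay in [0, 1] and nights are dark", {
  cfg <- generator_config(
    seed = 2,
    season_start = as.Date("2015-06-01"), season_end = as.Date("2015-08-31")
  )
  season <- generate_season(cfg)

  daily <- season$truth_daily
  expect_true(all(daily$fapar_true >= 0 & daily$fapar_true <= 1))
  expect_true(all(daily$ndvi_true >= -1 & daily$ndvi_true <= 1))

  tr <- season$truth
  expect_true(all(tr$spri_true >= 0 & tr$spri_true <= 1))
  expect_true(all(tr$rho532_true > 0 & tr$rho532_true < 1))
  expect_true(all(tr$reco_true >= 0))
  expect_true(all(tr$gpp_true >= 0))

  # WSN fractions
  w <- season$wsn
  t_frac <- w$ppfd_below_down / w$ppfd_above_down
  day <- is.finite(t_frac) & w$ppfd_above_down > 1
  expect_true(all(t_frac[day] > 0))

  # PPFD is exactly zero at night (whole 30-min window below the horizon;
  # elevation changes < 5 deg per half hour at this latitude)
  pos <- solar_position(cfg$site, season$flux$timestamp)
  night <- pos$elevation_deg < -5
  expect_true(any(night))
  expect_true(all(season$flux$ppfd[night] == 0))
})

test_that("with zero NEE noise the flux identity NEE = -GPP + Reco is exact", {
  cfg <- generator_config(
    seed = 5, nee_noise_sd = 0,
    season_start = as.Date("2015-07-01"), season_end = as.Date("2015-07-14")
  )
  season <- generate_season(cfg)
  expect_equal(season$flux$nee,
               -season$truth$gpp_true + season$truth$reco_true,
               tolerance = 1e-10)
})

test_that("maturity-month diurnal GPP tracks PPFD strongly", {
  cfg <- generator_config(
    seed = 6,
    season_start = as.Date("2015-06-01"), season_end = as.Date("2015-08-31")
  )
  season <- generate_season(cfg)
  tr <- season$truth |>
    dplyr::mutate(month = lubridate::month(timestamp)) |>
    dplyr::filter(ppfd > 0)
  for (m in 6:8) {
    sub <- tr[tr$month == m, ]
    expect_gt(stats::cor(sub$gpp_true, sub$ppfd)^2, 0.8)
  }
})

test_that("the configured transition day matches the noise-free NDVI curvature", {
  cfg <- generator_config(seed = 7)
  daily <- generate_season_truth(cfg)
  ph <- phenology_transition(daily$date, daily$ndvi_true)
  expect_true(ph$found)
  expect_lte(
    abs(as.numeric(ph$transition_date -
                     daily$date[match(cfg$senescence_inflection_doy,
                                      daily$doy)])),
    3
  )
})
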