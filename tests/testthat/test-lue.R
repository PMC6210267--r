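test_that("LUE is GPP/APAR with an APAR floor", {
  expect_equal(lue(10, 500), 0.02)
  expect_equal(lue(0, 500), 0)
  expect_true(is.na(lue(1, 10)))   # below the 50 umol floor
  expect_equal(lue(1, 100, apar_floor = 80), 0.01)
})

test_that("an identity proxy gives a perfect LUE model and exact GPP", {
  d <- tibble::tibble(
    lue = seq(0.01, 0.03, length.out = 50),
    apar = seq(200, 1500, length.out = 50)
  )
  d$spri <- d$lue # identity coupling
  m <- suppressWarnings(fit_lue_model(d, "spri")) # exact fit
  expect_equal(m$r2, 1)
  expect_equal(m$slope, 1, tolerance = 1e-9)
  expect_equal(m$intercept, 0, tolerance = 1e-12)
  pred <- predict_gpp(m, d$spri, d$apar)
  expect_equal(pred, d$lue * d$apar, tolerance = 1e-9)
  expect_equal(glance(m)$r.squared, 1)
})

test_that("a linear proxy coupling is recovered within 10%", {
  set.seed(14)
  spri <- runif(500, 0.4, 0.6)
  lue_true <- 0.05 * spri + 0.001
  d <- tibble::tibble(spri = spri, lue = lue_true + rnorm(500, 0, 0.002),
                      apar = runif(500, 100, 1500))
  m <- fit_lue_model(d, "spri")
  expect_lt(abs(m$slope - 0.05) / 0.05, 0.1)
  expect_lt(abs(m$intercept - 0.001), 0.002)
  # predicted vs true GPP r2 above the noise-implied ceiling minus 0.05
  gpp_true <- lue_true * d$apar
  gpp_obs <- d$lue * d$apar
  pred <- predict_gpp(m, d$spri, d$apar)
  ceiling <- stats::cor(gpp_true, gpp_obs)^2
  expect_gt(stats::cor(pred, gpp_obs)^2, ceiling - 0.05)
})

test_that("degenerate proxies and short series are rejected", {
  d <- tibble::tibble(spri = rep(0.5, 50), lue = runif(50, 0.01, 0.02))
  expect_error(fit_lue_model(d, "spri"), "degenerate")
  expect_error(fit_lue_model(d[1:5, ], "spri"), "at least 10")
})

test_that("predicted GPP/APAR equals modeled LUE up to clipping", {
  set.seed(15)
  d <- tibble::tibble(spri = runif(100, 0.3, 0.7))
  d$lue <- 0.04 * d$spri + rnorm(100, 0, 0.001)
  d$apar <- runif(100, 100, 1500)
  m <- fit_lue_model(d, "spri")
  pred <- predict_gpp(m, d$spri, d$apar)
  modeled_lue <- m$slope * d$spri + m$intercept
  keep <- modeled_lue > 0
  expect_equal(pred[keep] / d$apar[keep], modeled_lue[keep],
               tolerance = 1e-12)
  expect_true(all(pred >= 0))
})

test_that("stage scoping restricts the training records", {
  d <- tibble::tibble(
    spri = c(runif(30, 0.4, 0.6), runif(30, 0.3, 0.5)),
    stage = rep(c("maturity", "senescence"), each = 30)
  )
  d$lue <- ifelse(d$stage == "maturity", 0.05 * d$spri, 0.01 * d$spri) +
    rnorm(60, 0, 1e-4)
  m <- fit_lue_model(d, "spri", scope = "maturity")
  expect_equal(m$n, 30)
  expect_equal(m$slope, 0.05, tolerance = 0.05)
})

test_that("stratified correlations split season and stages correctly", {
  # exact linear relation: r2 = 1 in every scope
  d <- tibble::tibble(
    x = rep(seq(0, 1, length.out = 10), 2),
    stage = rep(c("maturity", "senescence"), each = 10)
  )
  d$y <- 2 * d$x + 1
  out <- stratified_correlation(d, "x", "y")
  expect_setequal(out$scope, c("season", "maturity", "senescence"))
  expect_true(all(out$r2 > 1 - 1e-12))
  expect_equal(out$n[out$scope == "season"], 20)

  # independent white noise: r2 below the sampling bound
  set.seed(16)
  d2 <- tibble::tibble(x = rnorm(500), y = rnorm(500),
                       stage = rep("maturity", 500))
  out2 <- stratified_correlation(d2, "x", "y")
  expect_lt(out2$r2[out2$scope == "season"], 0.02)

  # scopes with n < 3 are omitted
  d3 <- tibble::tibble(x = c(1, 2, 3, 4), y = c(1, 3, 2, 5),
                       stage = c(rep("maturity", 3), "senescence"))
  out3 <- stratified_correlation(d3, "x", "y")
  expect_false("senescence" %in% out3$scope)
})

test_that("stratified r2 matches direct computation on a constructed case", {
  # three points per stage with different stage means
  d <- tibble::tibble(
    x = c(1, 2, 3, 11, 12, 13),
    y = c(2.1, 3.9, 6.0, 21.5, 24.1, 25.8),
    stage = rep(c("maturity", "senescence"), each = 3)
  )
  out <- stratified_correlation(d, "x", "y")
  # independent oracle: explicit covariance formula
  r2_direct <- function(x, y) {
    sxy <- sum((x - mean(x)) * (y - mean(y)))
    sxy^2 / (sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  for (sc in out$scope) {
    sel <- if (sc == "season") rep(TRUE, 6) else d$stage == sc
    expect_equal(out$r2[out$scope == sc], r2_direct(d$x[sel], d$y[sel]),
                 tolerance = 1e-12)
  }
  # with differing stage means the season r2 reflects the pooled spread
  expect_gt(out$r2[out$scope == "season"],
            min(out$r2[out$scope != "season"]) - 1e-9)
})
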