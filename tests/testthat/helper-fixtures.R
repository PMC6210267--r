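# Shared fixture builders. Everything is generated in code at test time.

# A clean light-response window: `ndays` diurnal cycles of half-hourly
# NEE/PPFD/Tair built from the rectangular hyperbola + Q10 respiration,
# with optional iid noise. The default geometry mimics a long boreal
# summer day (light 04:00-20:00, peak PPFD 1600).
make_lr_window <- function(amax = 20, alpha = 0.03, r10 = 2, q10 = 2,
                           noise = 0, ndays = 2) {
  tod <- rep(seq(0, 23.5, by = 0.5), ndays)
  ppfd <- pmax(0, 1600 * sin(pi * (tod - 4) / 16)) * (tod > 4 & tod < 20)
  tair <- 12 + 6 * sin(2 * pi * (tod - 9) / 24)
  nee <- -(amax * alpha * ppfd) / (amax + alpha * ppfd) +
    r10 * q10^((tair - 10) / 10) +
    stats::rnorm(length(tod), 0, noise)
  tibble::tibble(nee = nee, ppfd = ppfd, tair = tair)
}

# Hand-built calibration set with known coefficients, for arithmetic and
# lookup-rule tests.
make_calset <- function(tab, bin_width = 3, min_n = 20) {
  defaults <- tibble::tibble(
    n = 100L, r2 = 0.9, illum_min = 15, illum_max = 100
  )
  for (col in names(defaults)) {
    if (!col %in% names(tab)) tab[[col]] <- defaults[[col]]
  }
  tab$bin_lower <- tab$bin * bin_width
  structure(tibble::as_tibble(tab),
    class = c("pri_calibration", class(tibble::tibble())),
    bin_width_deg = bin_width, min_n = min_n
  )
}

# Brute-force grid oracle for the light-response fit: coarse 4-D grid,
# refined 4 times around the incumbent. Independent of the Gauss-Newton
# path (no derivatives, no shared code).
grid_oracle_lr <- function(d, levels = 9, refinements = 4) {
  rng <- list(amax = c(5, 40), alpha = c(0.005, 0.1),
              r10 = c(0.5, 5), q10 = c(1.2, 3.5))
  best <- NULL
  for (ref in seq_len(refinements)) {
    gr <- expand.grid(lapply(rng, function(r) {
      seq(r[1], r[2], length.out = levels)
    }))
    sse <- apply(gr, 1, function(p) {
      sum((-(p[1] * p[2] * d$ppfd) / (p[1] + p[2] * d$ppfd) +
             p[3] * p[4]^((d$tair - 10) / 10) - d$nee)^2)
    })
    best <- gr[which.min(sse), ]
    rng <- lapply(seq_along(rng), function(k) {
      w <- diff(range(rng[[k]])) / (levels - 1)
      c(max(1e-6, best[[k]] - w), best[[k]] + w)
    })
    names(rng) <- c("amax", "alpha", "r10", "q10")
  }
  list(par = unlist(best), sse = min(sse))
}
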