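mk_hsf <- function(scale_yr, S, n_windows = 1L) {
  structure(data.frame(scale_yr = scale_yr, S = S,
                       n_windows = rep_len(n_windows, length(scale_yr))),
            class = c("haar_sf", "data.frame"))
}

test_that("band means select and average the right scales", {
  h <- mk_hsf(c(60, 100, 180, 100, 1000), c(2, 2, 2, 2, 2))
  expect_equal(band_mean(h, c(50, 200)), 2)
  h2 <- mk_hsf(c(100, 1000), c(1, 3))
  expect_equal(band_mean(h2, c(500, 2000)), 3)
  h3 <- mk_hsf(c(100, 400, 900), c(1, 2, 6))
  expect_equal(band_mean(h3, c(300, 1000)), 4)       # hand mean of 2 and 6
  expect_true(is.na(band_mean(h3, c(5000, 9000))))   # flagged, no error
})

test_that("a noiseless power law is fitted exactly by the gamma GLM", {
  grid <- default_scale_grid(seq(0, 6000, by = 100))
  h <- mk_hsf(grid, 0.1 * grid^0.3, n_windows = 5L)
  f <- fit_H(h, band = c(200, 3000))
  expect_equal(f$H, 0.3, tolerance = 1e-6)
  # the exponent is invariant under rescaling of S
  f2 <- fit_H(mk_hsf(grid, 7 * 0.1 * grid^0.3, 5L), band = c(200, 3000))
  expect_equal(f2$H, f$H, tolerance = 1e-9)
})

test_that("exponent fitting refuses degenerate structure functions", {
  expect_error(fit_H(mk_hsf(c(300, 600), c(1, 2)), c(200, 3000)),
               "insufficient scales")
  expect_error(fit_H(mk_hsf(c(300, 600, 1200), c(0, 0, 0)), c(200, 3000)),
               "degenerate")
})

test_that("the fluctuation exponent maps onto the spectral exponent", {
  expect_equal(h_to_beta(-0.5), 0)
  expect_equal(h_to_beta(0), 1)
  expect_equal(h_to_beta(0.25), 1.5)
})

test_that("sinusoidal detrending removes its own basis exactly", {
  t <- sort(runif(40, 0, 9000))
  y <- 1.4 * cos(2 * pi * t / 23000) - 0.6 * sin(2 * pi * t / 23000) + 2
  d <- detrend_sinusoid(t, y)
  expect_lt(max(abs(d$values)), 1e-9)
  expect_equal(d$amplitude, sqrt(1.4^2 + 0.6^2), tolerance = 1e-9)
  # constant input: zero residuals and zero amplitude
  d0 <- detrend_sinusoid(t, rep(5, length(t)))
  expect_lt(max(abs(d0$values)), 1e-9)
  expect_lt(d0$amplitude, 1e-9)
  # idempotence
  s <- make_irregular_series(50, seed = 81)
  d1 <- detrend_sinusoid(s$times, s$values)
  d2 <- detrend_sinusoid(d1$times, d1$values)
  expect_equal(d2$values, d1$values, tolerance = 1e-9)
})

test_that("detrending recovers a known amplitude under white noise", {
  set.seed(91)
  a <- 2; b <- -1; true_amp <- sqrt(a^2 + b^2)
  amps <- replicate(40, {
    t <- sort(runif(100, 0, 20000))
    y <- a * cos(2 * pi * t / 23000) + b * sin(2 * pi * t / 23000) + rnorm(100)
    detrend_sinusoid(t, y)$amplitude
  })
  se <- sd(amps) / sqrt(length(amps))
  expect_lt(abs(mean(amps) - true_amp), 3 * se + 0.02)
})

test_that("the Lomb-Scargle periodogram matches the FFT periodogram on a grid", {
  x <- gen_latent_signal(0, 256, seed = 11)
  ref <- fft_power(x$values)
  # same Fourier frequencies, unit spacing
  pg <- lomb_periodogram(x$times, x$values, freqs = ref$freq)
  expect_equal(pg$power, ref$power, tolerance = 1e-6)
  b_ls <- spectral_beta(x$times, x$values, freqs = ref$freq)
  expect_equal(b_ls, fft_beta(x$values), tolerance = 1e-6)
})

test_that("spectral slopes recover white-noise and 1/f exponents", {
  betas0 <- vapply(1:40, function(i) {
    x <- gen_latent_signal(-0.5, 256, seed = 900 + i)
    spectral_beta(x$times, x$values)
  }, numeric(1))
  expect_lt(abs(mean(betas0) - 0), 0.1)
  betas1 <- vapply(1:40, function(i) {
    x <- gen_latent_signal(0, 256, seed = 950 + i)
    spectral_beta(x$times, x$values)
  }, numeric(1))
  expect_lt(abs(mean(betas1) - 1), 0.1)
})

test_that("detrending flattens slow-trend series above the 2-ka scale", {
  # records carrying a slow 23-ka trend: after detrending, the fitted H
  # at multi-millennial scales drops relative to the raw fit
  diffs <- vapply(1:15, function(i) {
    x <- gen_latent_signal(0, 64, resolution = 260, seed = 1200 + i)
    t <- x$times
    y <- x$values + 3 * cos(2 * pi * (t + i * 1000) / 23000)
    h_raw <- fit_H(haar_sf(t, y), band = c(2000, 12000))$H
    d <- detrend_sinusoid(t, y)
    h_det <- fit_H(haar_sf(d$times, d$values), band = c(2000, 12000))$H
    h_det - h_raw
  }, numeric(1))
  expect_lt(mean(diffs), 0)
})
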