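#' Mean Haar fluctuation over a timescale band
#'
#' Unweighted mean of S(tau) over the scales falling inside the closed
#' band. The centennial variability S_C uses tau in [50, 200] yr and the
#' millennial variability S_M uses tau in [500, 2000] yr.
#'
#' @param hsf a `haar_sf`
#' @param band closed timescale interval `c(lo, hi)` in years
#' @return mean fluctuation, or `NA_real_` when no scale falls in the
#'   band (flagged missing, not an error)
#' @export
band_mean <- function(hsf, band) {
  sel <- hsf$scale_yr >= band[1] & hsf$scale_yr <= band[2]
  if (!any(sel)) return(NA_real_)
  mean(hsf$S[sel])
}

#' Fit the fluctuation exponent H by gamma GLM
#'
#' Assumes power-law scaling S(tau) ~ tau^H over the fit band and
#' estimates H with a gamma-family generalized linear model under a log
#' link, `E[S] = exp(c + H log tau)`, each scale weighted by its number
#' of contributing windows. A log-link GLM recovers a noiseless power
#' law exactly, and the gamma family matches the multiplicative error
#' structure of fluctuation estimates.
#'
#' @param hsf a `haar_sf`
#' @param band fit band in years (default `c(200, 3000)`, the
#'   centennial-to-millennial scaling H_CM)
#' @return list with `H`, `se_H`, `n_scales`
#' @export
fit_H <- function(hsf, band = c(200, 3000)) {
  sel <- hsf$scale_yr >= band[1] & hsf$scale_yr <= band[2] & hsf$n_windows >= 1
  d <- hsf[sel, , drop = FALSE]
  if (all(d$S <= 0)) stop("degenerate input: zero fluctuations at all scales in band")
  d <- d[d$S > 0, , drop = FALSE]
  if (nrow(d) < 3) stop("insufficient scales: need >= 3 usable scales in band")
  # a perfect (zero-dispersion) fit makes the gamma AIC evaluate
  # dgamma at an infinite shape; the coefficient estimates are unaffected
  fit <- withCallingHandlers(
    stats::glm(S ~ log(scale_yr), data = d,
               family = stats::Gamma(link = "log"), weights = d$n_windows),
    warning = function(w) {
      if (grepl("NaNs produced", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  co <- summary(fit)$coefficients
  list(H = unname(co[2, 1]), se_H = unname(co[2, 2]), n_scales = nrow(d))
}

#' Convert a fluctuation exponent to a spectral exponent
#'
#' For Gaussian processes the spectral exponent beta (power ~ f^-beta)
#' and the Haar fluctuation exponent H are related exactly by
#' `beta = 1 + 2 H`; white noise (beta = 0) has H = -0.5 and 1/f noise
#' (beta = 1) has H = 0.
#'
#' @param H fluctuation exponent
#' @return beta
#' @export
h_to_beta <- function(H) 1 + 2 * H

#' Summarize the scaling of one structure function
#'
#' Computes the centennial band mean S_C, the millennial band mean S_M,
#' the centennial-to-millennial exponent H_CM with its standard error,
#' beta = 1 + 2 H_CM, and the log-coverage of the fit band.
#'
#' @param hsf a `haar_sf`
#' @param band_C,band_M,band_H timescale bands in years
#' @return data.frame (one row) with `S_C`, `S_M`, `H_CM`, `se_H`,
#'   `beta`, `coverage_logfrac`, `n_scales_used`; exponent fields are NA
#'   when fewer than 3 usable scales fall in the fit band
#' @export
scaling_summary <- function(hsf, band_C = c(50, 200), band_M = c(500, 2000),
                            band_H = c(200, 3000)) {
  S_C <- band_mean(hsf, band_C)
  S_M <- band_mean(hsf, band_M)
  cov <- coverage_weight(hsf, band_H)
  H <- se <- NA_real_; n_used <- 0L
  ok <- sum(hsf$scale_yr >= band_H[1] & hsf$scale_yr <= band_H[2] & hsf$S > 0)
  if (ok >= 3) {
    f <- fit_H(hsf, band_H)
    H <- f$H; se <- f$se_H; n_used <- f$n_scales
  }
  data.frame(S_C = S_C, S_M = S_M, H_CM = H, se_H = se,
             beta = h_to_beta(H), coverage_logfrac = cov,
             n_scales_used = n_used)
}

#' Remove a fitted 23-ka sinusoid from a score series
#'
#' Fits `a cos(2 pi t / P) + b sin(2 pi t / P) + c` by ordinary least
#' squares on the irregular samples (amplitude and phase free through
#' the linear sin/cos parameterization) and returns the residuals. The
#' default period of 23 ka approximates the orbital precession cycle,
#' whose slow insolation trend otherwise steepens fluctuation estimates
#' at multi-millennial timescales.
#'
#' @param times sample ages (years BP), length >= 4
#' @param values series values
#' @param period sinusoid period in years (default 23000)
#' @return list of class `score_series`: `times`, `values` (residuals),
#'   `source = "detrended"`, plus `amplitude`, `phase`, `offset`
#' @export
detrend_sinusoid <- function(times, values, period = 23000) {
  if (length(times) < 4) stop("need at least 4 samples")
  w <- 2 * pi / period
  X <- cbind(1, cos(w * times), sin(w * times))
  if (qr(X)$rank < 3) stop("singular design: times do not resolve the sinusoid")
  fit <- stats::lm.fit(X, values)
  co <- fit$coefficients
  structure(
    list(times = times, values = unname(fit$residuals), source = "detrended",
         amplitude = unname(sqrt(co[2]^2 + co[3]^2)),
         phase = unname(atan2(co[3], co[2])), offset = unname(co[1])),
    class = "score_series"
  )
}

#' Lomb-Scargle periodogram of an irregular series
#'
#' Classical Scargle normalization with the time-offset correction; for
#' evenly sampled data evaluated at Fourier frequencies it coincides
#' with the standard periodogram. Values are centred before analysis.
#'
#' @param times sample ages, strictly increasing
#' @param values series values
#' @param freqs frequencies (cycles per year); default `k / T` for
#'   `k = 1 .. floor(n/2) - 1` with `T` the record span
#' @return data.frame with `freq`, `power`
#' @export
lomb_periodogram <- function(times, values, freqs = NULL) {
  n <- length(times)
  if (is.null(freqs)) {
    span <- times[n] - times[1]
    kmax <- max(floor(n / 2) - 1, 1)
    freqs <- (1:kmax) / span
  }
  y <- values - mean(values)
  power <- vapply(freqs, function(f) {
    w <- 2 * pi * f
    tau <- atan2(sum(sin(2 * w * times)), sum(cos(2 * w * times))) / (2 * w)
    ct <- cos(w * (times - tau)); st <- sin(w * (times - tau))
    0.5 * (sum(y * ct)^2 / sum(ct^2) + sum(y * st)^2 / sum(st^2))
  }, numeric(1))
  data.frame(freq = freqs, power = power)
}

#' Estimate the spectral exponent of a series
#'
#' Least-squares slope of log power versus log frequency on the
#' Lomb-Scargle periodogram; power ~ f^-beta. Serves as an independent
#' spectral route to the scaling exponent, related to the Haar exponent
#' by `beta = 1 + 2 H` for Gaussian processes.
#'
#' @param times sample ages, strictly increasing, length >= 16
#' @param values series values
#' @param freqs optional frequency grid (cycles per year)
#' @return estimated exponent `beta_hat` (a number)
#' @export
spectral_beta <- function(times, values, freqs = NULL) {
  if (length(times) < 16) stop("need at least 16 samples")
  pg <- lomb_periodogram(times, values, freqs)
  pg <- pg[pg$power > 0, ]
  fit <- stats::lm(log(power) ~ log(freq), data = pg)
  -unname(stats::coef(fit)[2])
}
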