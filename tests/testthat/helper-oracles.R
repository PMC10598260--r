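# Independent reference implementations used as oracles. These are
# deliberately naive (explicit loops, no shared code with the package)
# so that agreement is informative.

# Brute-force Haar structure function: enumerate every window explicitly.
haar_brute <- function(times, values, scales, min_per_half = 1) {
  t0_all <- times[1]
  t_last <- times[length(times)]
  tol <- 1e-9 * max(abs(t_last), 1)
  res <- list()
  for (tau in scales) {
    if (tau > t_last - t0_all + tol) next
    fl <- c()
    t0 <- t0_all
    while (t0 + tau <= t_last + tol) {
      first <- values[times >= t0 & times < t0 + tau / 2]
      second <- values[times >= t0 + tau / 2 & times < t0 + tau]
      if (length(first) >= min_per_half && length(second) >= min_per_half) {
        fl <- c(fl, abs(mean(second) - mean(first)))
      }
      t0 <- t0 + tau / 2
    }
    if (length(fl)) {
      res[[length(res) + 1L]] <- data.frame(scale_yr = tau, S = mean(fl),
                                            n_windows = length(fl))
    }
  }
  do.call(rbind, res)
}

# Classical FFT periodogram slope for a regular series (log-log least squares)
fft_beta <- function(values) {
  n <- length(values)
  y <- values - mean(values)
  p <- Mod(stats::fft(y))^2 / n
  k <- 1:(floor(n / 2) - 1)
  f <- k / n
  -unname(stats::coef(stats::lm(log(p[k + 1]) ~ log(f)))[2])
}

# FFT periodogram power at Fourier frequencies (for direct comparison)
fft_power <- function(values) {
  n <- length(values)
  y <- values - mean(values)
  p <- Mod(stats::fft(y))^2 / n
  k <- 1:(floor(n / 2) - 1)
  data.frame(freq = k / n, power = p[k + 1])
}

# Direct weighted Pearson correlation by the textbook formula
weighted_r_direct <- function(x, y, w) {
  sw <- sum(w)
  mx <- sum(w * x) / sw
  my <- sum(w * y) / sw
  cov <- sum(w * (x - mx) * (y - my)) / sw
  vx <- sum(w * (x - mx)^2) / sw
  vy <- sum(w * (y - my)^2) / sw
  cov / sqrt(vx * vy)
}

# a tiny irregular series for reuse
make_irregular_series <- function(n, seed) {
  set.seed(seed)
  times <- sort(runif(n, 0, 100))
  while (any(diff(times) <= 0)) times <- sort(runif(n, 0, 100))
  list(times = times, values = rnorm(n))
}

# quick synthetic record with known ground truth
quick_record <- function(seed = 1, mixture = 0.5, H_true = 0, ...) {
  p <- default_profiles()
  cfg <- synthetic_config(mixture = mixture, H_true = H_true, seed = seed, ...)
  gen_pollen_record(cfg, p$forest, p$open)
}
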