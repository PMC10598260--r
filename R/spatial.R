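#' Grid a per-site metric onto a fixed graticule
#'
#' Cells are `cell_deg` x `cell_deg` boxes with edges anchored at 0
#' (multiples of `cell_deg`); a site belongs to the cell whose edges
#' satisfy `edge <= coord < edge + cell_deg`. The cell value is the mean
#' of its member sites' metric.
#'
#' @param sites data.frame with `lat`, `lon` and the metric column
#' @param metric name of the metric column
#' @param cell_deg cell size in degrees (default 4)
#' @return data.frame with `lat_bin`, `lon_bin` (lower cell edges),
#'   `value` (cell mean), `n_sites`
#' @export
grid_metric <- function(sites, metric, cell_deg = 4) {
  ok <- is.finite(sites[[metric]])
  s <- sites[ok, , drop = FALSE]
  lat_bin <- floor(s$lat / cell_deg) * cell_deg
  lon_bin <- floor(s$lon / cell_deg) * cell_deg
  key <- paste(lat_bin, lon_bin)
  agg <- tapply(s[[metric]], key, mean)
  cnt <- tapply(s[[metric]], key, length)
  first <- !duplicated(key)
  d <- data.frame(lat_bin = lat_bin[first], lon_bin = lon_bin[first])
  d$value <- as.numeric(agg[key[first]])
  d$n_sites <- as.integer(cnt[key[first]])
  d[order(d$lat_bin, d$lon_bin), ]
}

# Moran's I statistic for a given (row-standardized) weight matrix
moran_stat <- function(values, W) {
  z <- values - mean(values)
  n <- length(z)
  (n / sum(W)) * as.numeric(t(z) %*% W %*% z) / sum(z^2)
}

# inverse great-circle-distance weights, row-standardized, zero diagonal
inv_distance_weights <- function(lats, lons) {
  d <- geosphere::distm(cbind(lons, lats)) / 1000  # km
  W <- 1 / d
  diag(W) <- 0
  W[!is.finite(W)] <- 0
  rs <- rowSums(W)
  rs[rs == 0] <- 1
  W / rs
}

#' Moran's I spatial autocorrelation of a site metric
#'
#' Standard Moran's I with row-standardized inverse great-circle
#' distance weights (self-weight 0). The expected value under spatial
#' randomness is `-1/(n-1)`. Significance is reported both by the
#' normal approximation (via [ape::Moran.I()]) and by a seeded
#' permutation null.
#'
#' @param values per-site metric (length n >= 3, not all equal)
#' @param lats,lons site coordinates (decimal degrees)
#' @param n_perm number of permutations (default 999)
#' @param seed integer seed for the permutation null
#' @param weights optional precomputed weight matrix (row-standardized,
#'   zero diagonal); overrides the inverse-distance default
#' @return list of class `moran_result`: `I`, `expected_I`, `sd_norm`,
#'   `p_norm` (two-sided normal approximation), `p_perm` (two-sided
#'   permutation p), `perm_mean` (mean of the permuted statistics), `n`
#' @export
morans_i <- function(values, lats, lons, n_perm = 999, seed = NULL,
                     weights = NULL) {
  n <- length(values)
  if (n < 3) stop("need at least 3 sites")
  if (stats::sd(values) == 0) stop("constant values: zero variance")
  W <- weights %||% inv_distance_weights(lats, lons)
  a <- ape::Moran.I(values, W, alternative = "two.sided")
  I_obs <- moran_stat(values, W)
  perm_I <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) moran_stat(sample(values), W),
           numeric(1))
  })
  e <- -1 / (n - 1)
  p_perm <- (1 + sum(abs(perm_I - e) >= abs(I_obs - e))) / (1 + n_perm)
  structure(
    list(I = I_obs, expected_I = e, sd_norm = a$sd, p_norm = a$p.value,
         p_perm = p_perm, perm_mean = mean(perm_I),
         perm_se = stats::sd(perm_I) / sqrt(n_perm), n = n),
    class = "moran_result"
  )
}

#' Coverage-weighted Pearson correlation
#'
#' Weighted Pearson correlation using weighted means, variances and
#' covariance; significance by a seeded permutation of `y` (weights stay
#' attached to the `x` positions). With equal weights this reduces
#' exactly to the ordinary Pearson correlation.
#'
#' @param x,y numeric vectors (length >= 3)
#' @param w nonnegative weights, not all zero (e.g. per-site
#'   [coverage_weight()])
#' @param n_perm number of permutations (default 9999)
#' @param seed integer seed
#' @return list of class `weighted_corr`: `r`, `p_value` (two-sided
#'   permutation p), `n`
#' @export
weighted_correlation <- function(x, y, w, n_perm = 9999, seed = NULL) {
  if (length(x) != length(y) || length(x) != length(w)) {
    stop("x, y and w must have equal length")
  }
  if (length(x) < 3) stop("need at least 3 observations")
  if (any(w < 0)) stop("weights must be nonnegative")
  if (sum(w) == 0) stop("weights must not all be zero")
  r_obs <- weighted_r(x, y, w)
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) weighted_r(x, sample(y), w),
           numeric(1))
  })
  p <- (1 + sum(abs(perm) >= abs(r_obs))) / (1 + n_perm)
  structure(list(r = r_obs, p_value = p, n = length(x)),
            class = "weighted_corr")
}

weighted_r <- function(x, y, w) {
  w <- w / sum(w)
  mx <- sum(w * x); my <- sum(w * y)
  vx <- sum(w * (x - mx)^2); vy <- sum(w * (y - my)^2)
  if (vx == 0 || vy == 0) stop("zero weighted variance")
  sum(w * (x - mx) * (y - my)) / sqrt(vx * vy)
}

#' Log-timescale coverage of a fit band
#'
#' Fraction of the band covered in log timescale by the available
#' scales: `(log t_max_avail - log t_min_avail) / (log hi - log lo)`,
#' clipped to [0, 1]; zero when no scale falls in the band. Used to
#' weight sites in correlation analyses by how well their record
#' resolves the band.
#'
#' @param hsf a `haar_sf`
#' @param band timescale band `c(lo, hi)` in years
#' @return coverage fraction in [0, 1]
#' @export
coverage_weight <- function(hsf, band) {
  sel <- hsf$scale_yr >= band[1] & hsf$scale_yr <= band[2]
  if (!any(sel)) return(0)
  avail <- hsf$scale_yr[sel]
  frac <- (log(max(avail)) - log(min(avail))) / (log(band[2]) - log(band[1]))
  min(max(frac, 0), 1)
}
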