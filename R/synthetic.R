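#' Synthesize a Gaussian series with a prescribed power-law spectrum
#'
#' Generates a regularly sampled, zero-mean, unit-variance Gaussian series
#' whose expected power spectral density follows \eqn{P(f) \propto
#' f^{-\beta}} with \eqn{\beta = 1 + 2H}. Synthesis is by Fourier
#' filtering: complex Gaussian spectral coefficients with amplitudes
#' proportional to \eqn{f^{-\beta/2}} and random phases are inverted to
#' the time domain. For \eqn{H = -0.5} (\eqn{\beta = 0}) the result is
#' exactly white Gaussian noise; \eqn{H = 0} gives 1/f ("pink") noise.
#'
#' The fluctuation exponent H is the log-log slope of the first-order
#' Haar structure function; H < 0 marks a stationary process converging
#' to a mean, H > 0 a drifting one.
#'
#' @param H_true target fluctuation exponent, in \eqn{[-0.5, 1]}
#' @param n number of samples (>= 16)
#' @param resolution sampling interval in years (default 1)
#' @param seed integer seed; same seed and parameters give identical output
#' @return object of class `latent_signal`: list with `times` (years BP,
#'   ascending from 0), `values` (standardized to zero mean, unit
#'   variance), `H_true`, `seed`
#' @examples
#' wn <- gen_latent_signal(-0.5, 256, seed = 1)
#' var(wn$values)
#' @export
gen_latent_signal <- function(H_true, n, resolution = 1, seed = NULL) {
  if (!is.numeric(H_true) || length(H_true) != 1L || H_true < -0.5 || H_true > 1) {
    stop("`H_true` must lie in [-0.5, 1]; the spectral synthesis is not designed beyond this range")
  }
  if (n < 16) stop("`n` must be at least 16")
  n <- as.integer(n)
  beta <- 1 + 2 * H_true

  values <- with_seed(seed, {
    m <- n %/% 2L
    f <- (1:m) / n                      # cycles per sample
    amp <- f^(-beta / 2)
    re <- stats::rnorm(m)
    im <- stats::rnorm(m)
    z <- complex(real = re, imaginary = im) / sqrt(2) * amp
    # Nyquist coefficient must be real for even n
    if (n %% 2L == 0L) z[m] <- complex(real = re[m] * amp[m], imaginary = 0)
    spec <- complex(real = numeric(n))
    spec[2:(m + 1L)] <- z
    k_conj <- if (n %% 2L == 0L) seq_len(m - 1L) else seq_len(m)
    spec[n + 1L - k_conj] <- Conj(z[k_conj])
    x <- Re(stats::fft(spec, inverse = TRUE)) / sqrt(n)
    (x - mean(x)) / stats::sd(x)
  })

  structure(
    list(times = (seq_len(n) - 1) * resolution,
         values = values, H_true = H_true, seed = seed),
    class = "latent_signal"
  )
}

#' Draw irregular sample ages with heavy-tailed spacing
#'
#' Emulates the irregular temporal sampling of sediment pollen records:
#' sample ages are cumulative sums of gamma-distributed increments whose
#' dispersion is set so that the largest gap in a record is, in
#' expectation, about `gap_factor` times the mean spacing. Increments are
#' rescaled so the realized mean spacing equals `mean_resolution`
#' exactly (total span `(n_samples - 1) * mean_resolution`).
#'
#' @param n_samples number of samples (>= 2)
#' @param mean_resolution mean spacing in years
#' @param gap_factor target ratio of largest gap to mean spacing;
#'   `gap_factor <= 1` degenerates to a regular grid
#' @param start age of the youngest sample (years BP; default 0)
#' @param seed integer seed
#' @return strictly increasing numeric vector of ages (years BP)
#' @export
gen_irregular_times <- function(n_samples, mean_resolution = 260,
                                gap_factor = 2, start = 0, seed = NULL) {
  if (n_samples < 2) stop("`n_samples` must be at least 2")
  n_inc <- n_samples - 1L
  if (gap_factor <= 1) {
    return(start + (0:n_inc) * mean_resolution)
  }
  # choose the gamma shape so the (1 - 1/n) quantile of the increment
  # distribution -- a proxy for the expected maximum of n draws -- sits
  # at gap_factor times the mean
  shape <- gamma_shape_for_gap(gap_factor, n_inc)
  inc <- with_seed(seed, stats::rgamma(n_inc, shape = shape, rate = shape))
  inc <- inc / mean(inc) * mean_resolution
  start + c(0, cumsum(inc))
}

# solve qgamma(1 - 1/n, shape, rate = shape) = gap_factor for shape;
# the quantile is decreasing in shape on [0.5, Inf), which covers every
# realistic gap request (below shape ~0.5 the spacing distribution would
# be dominated by near-zero increments)
gamma_shape_for_gap <- function(gap_factor, n) {
  p <- 1 - 1 / max(n, 2)
  f <- function(k) stats::qgamma(p, shape = k, rate = k) - gap_factor
  lo <- 0.5
  if (f(lo) <= 0) return(lo)
  stats::uniroot(f, c(lo, 1e3), tol = 1e-8)$root
}

#' Configuration for a synthetic pollen record
#'
#' Bundles the knobs of the generator. Defaults emulate the sampling
#' characteristics typical of Holocene records retained for variability
#' analysis: mean resolution ~260 yr, largest gaps ~2x the mean spacing,
#' coverage ~6000 yr, and a conventional pollen count sum of 300 grains
#' per sample.
#'
#' @param n_taxa number of taxa
#' @param n_samples samples per record
#' @param mean_resolution mean sample spacing, years
#' @param gap_factor largest-gap / mean-spacing target (dimensionless)
#' @param count_total pollen grains counted per sample
#' @param mixture weight of biome-i profile in the base composition, in [0,1]
#' @param H_true fluctuation exponent of the latent compositional driver
#' @param amplitude standard-deviation scale of the latent driver on the
#'   log-ratio (softmax) scale
#' @param start age of the youngest sample, years BP
#' @param seed integer seed
#' @return list of class `synthetic_config`; `beta_true = 1 + 2 * H_true`
#'   and `coverage = (n_samples - 1) * mean_resolution` are derived
#' @export
synthetic_config <- function(n_taxa = 12, n_samples = 24, mean_resolution = 260,
                             gap_factor = 2, count_total = 300, mixture = 1,
                             H_true = 0, amplitude = 2, start = 1900,
                             seed = NULL) {
  stopifnot(n_taxa >= 2, n_samples >= 2, mean_resolution > 0,
            count_total >= 1, mixture >= 0, mixture <= 1)
  coverage <- (n_samples - 1) * mean_resolution
  if (coverage < n_samples) stop("coverage must be at least 1 yr per sample")
  structure(
    list(n_taxa = n_taxa, n_samples = n_samples,
         mean_resolution = mean_resolution, gap_factor = gap_factor,
         count_total = count_total, mixture = mixture, H_true = H_true,
         beta_true = 1 + 2 * H_true, amplitude = amplitude,
         coverage = coverage, start = start, seed = seed),
    class = "synthetic_config"
  )
}

#' Reference taxa profiles for a two-biome world
#'
#' Two compositional profiles over a shared list of common northern
#' hemisphere pollen taxa: a forest profile dominated by arboreal taxa
#' (Pinus, Picea, Betula, Quercus, Abies, Alnus) and an open-land
#' profile dominated by non-arboreal taxa (Poaceae, Artemisia,
#' Cyperaceae, Amaranthaceae). Each profile sums to 1.
#'
#' @return named list with elements `forest` and `open`, each a named
#'   numeric vector over the same taxa
#' @export
default_profiles <- function() {
  taxa <- c("Pinus", "Picea", "Betula", "Quercus", "Abies", "Alnus",
            "Larix", "Tsuga", "Poaceae", "Artemisia", "Cyperaceae",
            "Amaranthaceae")
  forest <- c(0.30, 0.18, 0.14, 0.10, 0.07, 0.06,
              0.03, 0.02, 0.04, 0.02, 0.03, 0.01)
  open   <- c(0.08, 0.02, 0.05, 0.01, 0.01, 0.02,
              0.01, 0.00, 0.32, 0.22, 0.16, 0.10)
  names(forest) <- names(open) <- taxa
  list(forest = forest / sum(forest), open = open / sum(open))
}

#' Generate one synthetic pollen record
#'
#' Draws multinomial pollen counts from a time-varying composition. The
#' base composition is `mixture * profile_i + (1 - mixture) * profile_j`;
#' a latent Gaussian signal with fluctuation exponent `H_true` perturbs
#' it along the profile-difference direction through a softmax link, so
#' proportions stay in the simplex at any amplitude. The latent signal is
#' synthesized on a fine regular grid (quarter of the mean resolution)
#' and linearly interpolated to the irregular sample ages.
#'
#' @param config a [synthetic_config()]
#' @param profile_i,profile_j nonnegative taxa profiles summing to 1 on a
#'   shared taxon list
#' @param site_id site identifier
#' @param lat,lon site coordinates (decimal degrees)
#' @return a [pollen_record()]; attributes `mixture`, `H_true` and
#'   `latent` (driver values at the sample ages) carry the ground truth
#'   for recovery tests
#' @export
gen_pollen_record <- function(config, profile_i, profile_j = NULL,
                              site_id = "synth_01", lat = 55, lon = 10) {
  if (is.null(profile_j)) profile_j <- profile_i
  if (length(profile_i) != length(profile_j)) {
    stop("taxa profiles must have equal length")
  }
  if (any(profile_i < 0) || any(profile_j < 0)) stop("profiles must be nonnegative")
  profile_i <- profile_i / sum(profile_i)
  profile_j <- profile_j / sum(profile_j)
  taxa <- names(profile_i) %||% paste0("taxon_", seq_along(profile_i))

  seeds <- derive_seeds(config$seed %||% stats::runif(1, 1, 2^30), 3)
  times <- gen_irregular_times(config$n_samples, config$mean_resolution,
                               config$gap_factor, start = config$start,
                               seed = seeds[1])

  # latent driver on a fine regular grid, interpolated to sample ages
  dt <- config$mean_resolution / 4
  n_lat <- 2^ceiling(log2(config$coverage / dt + 2))
  n_lat <- max(n_lat, 16L)
  latent <- gen_latent_signal(config$H_true, n_lat, resolution = dt,
                              seed = seeds[2])
  z <- stats::approx(config$start + latent$times, latent$values,
                     xout = times, rule = 2)$y

  base <- config$mixture * profile_i + (1 - config$mixture) * profile_j
  dir <- profile_i - profile_j   # all-zero when profiles coincide: no perturbation
  eta0 <- ifelse(base > 0, log(base), -Inf)
  eta <- outer(config$amplitude * z, dir) + matrix(eta0, length(z),
                                                   length(base), byrow = TRUE)
  probs <- softmax_rows(eta)

  counts <- with_seed(seeds[3], {
    t(apply(probs, 1L, function(p) stats::rmultinom(1, config$count_total, p)))
  })
  colnames(counts) <- taxa

  rec <- pollen_record(site_id = site_id, lat = lat, lon = lon,
                       times = times, taxa = taxa, counts = counts)
  attr(rec, "mixture") <- config$mixture
  attr(rec, "H_true") <- config$H_true
  attr(rec, "latent") <- z
  rec
}

#' Generate a labelled surface-sample set
#'
#' Stands in for recent pollen samples (ages between 500 yr BP and the
#' present) whose sites carry biome / land-cover intersection-class
#' labels. Each record gets 1--5 samples with ages in [-60, 500] BP and
#' multinomial counts from its biome's profile.
#'
#' @param n_records_per_biome records per biome class
#' @param profiles named list of taxa profiles, one per biome class
#' @param class_labels character vector of class labels, defaults to
#'   `names(profiles)`
#' @param count_total grains per sample
#' @param seed integer seed
#' @return list with `records` (list of [pollen_record()]) and `meta`
#'   (data.frame: site_id, lat, lon, class)
#' @export
gen_surface_set <- function(n_records_per_biome, profiles,
                            class_labels = names(profiles),
                            count_total = 300, seed = NULL) {
  if (length(profiles) < 1) stop("need at least one biome class")
  stopifnot(length(class_labels) == length(profiles))
  n_tot <- n_records_per_biome * length(profiles)
  seeds <- derive_seeds(seed %||% stats::runif(1, 1, 2^30), n_tot + 1)

  records <- list(); meta <- list(); idx <- 0L
  coords <- with_seed(seeds[n_tot + 1], {
    data.frame(lat = stats::runif(n_tot, 40, 70),
               lon = stats::runif(n_tot, -120, 140))
  })
  for (b in seq_along(profiles)) {
    prof <- profiles[[b]]
    prof <- prof / sum(prof)
    taxa <- names(prof) %||% paste0("taxon_", seq_along(prof))
    for (r in seq_len(n_records_per_biome)) {
      idx <- idx + 1L
      sid <- sprintf("surf_%s_%02d", class_labels[b], r)
      rec <- with_seed(seeds[idx], {
        k <- sample(1:5, 1)
        ages <- sort(stats::runif(k, -60, 500))
        cnt <- t(sapply(seq_len(k), function(i) {
          stats::rmultinom(1, count_total, prof)[, 1]
        }))
        colnames(cnt) <- taxa
        pollen_record(site_id = sid, lat = coords$lat[idx],
                      lon = coords$lon[idx], times = ages, taxa = taxa,
                      counts = cnt,
                      class_labels = list(class = class_labels[b]))
      })
      records[[idx]] <- rec
      meta[[idx]] <- data.frame(site_id = sid, lat = coords$lat[idx],
                                lon = coords$lon[idx],
                                class = class_labels[b],
                                stringsAsFactors = FALSE)
    }
  }
  list(records = records, meta = do.call(rbind, meta))
}

#' Generate a two-biome world of fossil records
#'
#' Convenience wrapper: `n_records` fossil records whose mixture between
#' the forest and open-land profiles is spread evenly over
#' `mixture_range`, each with its own latent driver of exponent
#' `H_true`. Coordinates are drawn over the extratropical northern
#' hemisphere.
#'
#' @param n_records number of records
#' @param H_true fluctuation exponent of the latent driver (scalar or
#'   per-record vector)
#' @param amplitude latent-driver amplitude (scalar or per-record
#'   vector), e.g. to make open-land records more variable
#' @param mixture_range range of mixtures toward the forest profile
#' @param config_args extra arguments passed to [synthetic_config()]
#' @param seed integer seed
#' @return list with `records` and `meta` (site_id, lat, lon,
#'   true_mixture, true_H)
#' @export
gen_two_biome_world <- function(n_records = 50, H_true = 0, amplitude = 2,
                                mixture_range = c(0.1, 0.9),
                                config_args = list(), seed = NULL) {
  profs <- default_profiles()
  H_true <- rep_len(H_true, n_records)
  amplitude <- rep_len(amplitude, n_records)
  mixtures <- seq(mixture_range[1], mixture_range[2],
                  length.out = n_records)
  seeds <- derive_seeds(seed %||% stats::runif(1, 1, 2^30), n_records + 1)
  coords <- with_seed(seeds[n_records + 1], {
    data.frame(lat = stats::runif(n_records, 30, 70),
               lon = stats::runif(n_records, -130, 150))
  })
  records <- vector("list", n_records)
  for (i in seq_len(n_records)) {
    cfg <- do.call(synthetic_config,
                   c(list(mixture = mixtures[i], H_true = H_true[i],
                          amplitude = amplitude[i], seed = seeds[i]),
                     config_args))
    records[[i]] <- gen_pollen_record(cfg, profs$forest, profs$open,
                                      site_id = sprintf("site_%03d", i),
                                      lat = coords$lat[i], lon = coords$lon[i])
  }
  meta <- data.frame(site_id = sprintf("site_%03d", seq_len(n_records)),
                     lat = coords$lat, lon = coords$lon,
                     true_mixture = mixtures, true_H = H_true,
                     stringsAsFactors = FALSE)
  list(records = records, meta = meta)
}
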