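#' Pipeline configuration
#'
#' Bundles every analysis parameter with its standard default: the 8-2
#' ka BP analysis window, the record filter (>= 6 in-window samples,
#' north of 25 N), the Haar options, the scaling bands (centennial
#' S_C over [50, 200] yr, millennial S_M over [500, 2000] yr, exponent
#' H_CM fitted over [200, 3000] yr), the 23-ka detrend period, the
#' quantile count k = 5 and the confidence cap n_max = 100.
#'
#' @param window analysis window, years BP
#' @param min_samples,min_lat record filter thresholds
#' @param band_C,band_M,band_H scaling bands, years
#' @param detrend_period sinusoid period in years, or `NA` to skip
#'   detrending
#' @param min_per_half minimum samples per half-window in the Haar
#'   analysis. The pipeline default is 2: single-sample halves measure
#'   raw increments rather than half-means, which inflates fluctuation
#'   estimates near the record resolution and biases scaling fits low
#'   on sparse records
#' @param k number of quantile groups
#' @param n_max cap on effective record count in confidence intervals
#' @param recent_window surface-sample window, years BP
#' @param seed integer seed for permutation tests
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(window = c(2000, 8000), min_samples = 6,
                            min_lat = 25, band_C = c(50, 200),
                            band_M = c(500, 2000), band_H = c(200, 3000),
                            detrend_period = NA, min_per_half = 2, k = 5,
                            n_max = 100, recent_window = c(-60, 500),
                            seed = 1L) {
  stopifnot(window[1] < window[2], k >= 2)
  structure(
    list(window = window, min_samples = min_samples, min_lat = min_lat,
         band_C = band_C, band_M = band_M, band_H = band_H,
         detrend_period = detrend_period, min_per_half = min_per_half,
         k = k, n_max = n_max,
         recent_window = recent_window, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the full variability analysis
#'
#' Orchestrates: filter records to the analysis window; per record, PC1
#' of the square-rooted assemblage, optional 23-ka sinusoidal
#' detrending, Haar structure function and scaling summary; typical
#' assemblages and a difference axis from the labelled surface set;
#' projection of fossil records onto the axis and mean biome scores;
#' quantile grouping with per-group aggregated structure functions; the
#' coverage-weighted correlations of S_C, S_M and H_CM against the mean
#' biome score; and Moran's I of each variability metric.
#'
#' @param records list of [pollen_record()] (fossil records)
#' @param surface list with `records` and `meta` as from
#'   [gen_surface_set()]; `NULL` skips the biome-axis stages
#' @param axes list of axis specifications, each
#'   `list(i = <classes>, j = <classes>, id_i =, id_j =, weights_i =, weights_j =)`;
#'   default one forest-vs-open axis using classes "forest" and "open"
#' @param config a [pipeline_config()]
#' @return list with `records` (filtered), `pc1` (per-site score table),
#'   `hsf` (per-site `haar_sf`), `scaling` (per-site summary table),
#'   `hsf_mean` (aggregated), `axes`, `biome_scores`, `groups`,
#'   `group_hsf`, `correlations`, `moran`, `manifest`
#' @export
run_pipeline <- function(records, surface = NULL, axes = NULL,
                         config = pipeline_config()) {
  filtered <- filter_records(records, config$min_samples, config$min_lat,
                             config$window)
  report <- attr(filtered, "filter_report")
  if (!length(filtered)) stop("stage filter_records: no record survived filtering")

  pc1_tab <- list(); hsf_list <- list(); scal <- list()
  for (r in filtered) {
    res <- tryCatch({
      s <- pc1_scores(r)
      if (!is.na(config$detrend_period)) {
        s <- detrend_sinusoid(s$times, s$values, config$detrend_period)
      }
      h <- haar_sf(s$times, s$values, min_per_half = config$min_per_half)
      list(scores = s, hsf = h, summary = scaling_summary(
        h, config$band_C, config$band_M, config$band_H))
    }, error = function(e) {
      stop("stage per_record (site ", r$site_id, "): ", conditionMessage(e))
    })
    pc1_tab[[r$site_id]] <- data.frame(
      site_id = r$site_id, age_bp = res$scores$times,
      pc1_score = res$scores$values)
    hsf_list[[r$site_id]] <- res$hsf
    srow <- res$summary
    srow$site_id <- r$site_id
    srow$coverage_H <- coverage_weight(res$hsf, config$band_H)
    srow$coverage_C <- coverage_weight(res$hsf, config$band_C)
    srow$coverage_M <- coverage_weight(res$hsf, config$band_M)
    scal[[r$site_id]] <- srow
  }
  pc1_tab <- do.call(rbind, pc1_tab)
  scal <- do.call(rbind, scal)
  rownames(scal) <- NULL
  hsf_mean <- aggregate_hsf(hsf_list, n_max = config$n_max)

  out <- list(records = filtered, filter_report = report, pc1 = pc1_tab,
              hsf = hsf_list, scaling = scal, hsf_mean = hsf_mean)

  if (!is.null(surface)) {
    recent <- recent_assemblages(surface$records, config$recent_window)
    if (is.null(axes)) {
      axes <- list(list(i = "forest", j = "open",
                        id_i = "Fo", id_j = "Op"))
    }
    axis_objs <- list(); score_tabs <- list()
    for (ax in axes) {
      a_i <- typical_assemblage(recent, ax$i, ax$weights_i %||% NULL,
                                biome_id = ax$id_i)
      a_j <- typical_assemblage(recent, ax$j, ax$weights_j %||% NULL,
                                biome_id = ax$id_j)
      axis <- difference_axis(a_i, a_j)
      axis_objs[[axis$axis_id]] <- axis
      rows <- lapply(filtered, function(r) {
        ss <- project_scores(r, axis)
        ms <- mean_score(ss, config$window)
        data.frame(site_id = r$site_id, axis_id = axis$axis_id,
                   u_bar = ms$u_bar,
                   n_samples_in_window = ms$n_samples_in_window,
                   region = r$region)
      })
      score_tabs[[axis$axis_id]] <- do.call(rbind, rows)
    }
    biome_scores <- do.call(rbind, score_tabs)
    rownames(biome_scores) <- NULL

    first_axis <- names(axis_objs)[1]
    bs1 <- biome_scores[biome_scores$axis_id == first_axis, ]
    grp <- quantile_groups(bs1$u_bar, config$k)
    groups <- data.frame(site_id = bs1$site_id, axis_id = first_axis,
                         u_bar = bs1$u_bar, quantile_group = grp)
    group_hsf <- aggregate_by_quantile(hsf_list, bs1, k = config$k,
                                       n_max = config$n_max,
                                       band_H = config$band_H)

    merged <- merge(scal, bs1[, c("site_id", "u_bar")], by = "site_id")
    corr <- list()
    for (metric in c("S_C", "S_M", "H_CM")) {
      wcol <- switch(metric, S_C = "coverage_C", S_M = "coverage_M",
                     H_CM = "coverage_H")
      ok <- is.finite(merged[[metric]]) & merged[[wcol]] > 0
      if (sum(ok) >= 3) {
        wc <- weighted_correlation(merged$u_bar[ok], merged[[metric]][ok],
                                   merged[[wcol]][ok], seed = config$seed)
        corr[[metric]] <- data.frame(axis_id = first_axis, metric = metric,
                                     r = wc$r, p_perm = wc$p_value, n = wc$n)
      }
    }
    out$biome_scores <- biome_scores
    out$axes <- axis_objs
    out$groups <- groups
    out$group_hsf <- group_hsf
    out$correlations <- do.call(rbind, corr)
  }

  site_meta <- data.frame(site_id = vapply(filtered, `[[`, "", "site_id"),
                          lat = vapply(filtered, `[[`, 0, "lat"),
                          lon = vapply(filtered, `[[`, 0, "lon"))
  sc <- merge(site_meta, scal, by = "site_id")
  moran <- list()
  for (metric in c("S_C", "S_M", "H_CM")) {
    ok <- is.finite(sc[[metric]])
    if (sum(ok) >= 3 && stats::sd(sc[[metric]][ok]) > 0) {
      m <- morans_i(sc[[metric]][ok], sc$lat[ok], sc$lon[ok],
                    seed = config$seed)
      moran[[metric]] <- data.frame(metric = metric, morans_I = m$I,
                                    expected_I = m$expected_I,
                                    p_norm = m$p_norm, p_perm = m$p_perm,
                                    n = m$n)
    }
  }
  out$moran <- do.call(rbind, moran)

  out$manifest <- list(
    config = unclass(config),
    config_hash = config_hash(config),
    n_records_input = report$n_input,
    n_records_retained = report$n_retained,
    r_version = as.character(getRversion())
  )
  out
}

config_hash <- function(config) {
  s <- paste(deparse(unclass(config)), collapse = "")
  # small rolling hash; enough to tag outputs with their configuration
  sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %% 1e9
}

#' Aggregate structure functions by biome-score quantile
#'
#' Splits sites into k equal-count groups by their mean biome score,
#' averages the member structure functions per group, and fits the
#' centennial-to-millennial exponent of each group mean. Scales backed
#' by fewer than 10 contributing records are flagged (`sparse`).
#'
#' @param hsf_per_site named list of `haar_sf` (names = site_id)
#' @param biome_scores data.frame with `site_id` and `u_bar`
#' @param k number of quantile groups (default 5)
#' @param n_max confidence-interval cap (default 100)
#' @param band_H exponent fit band (default `c(200, 3000)`)
#' @param sparse_threshold records below which a scale is flagged
#' @return list per group: `group`, `hsf` (aggregated, with `sparse`
#'   flag column), `H`, `se_H`, `n_sites`
#' @export
aggregate_by_quantile <- function(hsf_per_site, biome_scores, k = 5,
                                  n_max = 100, band_H = c(200, 3000),
                                  sparse_threshold = 10) {
  common <- intersect(names(hsf_per_site), biome_scores$site_id)
  bs <- biome_scores[match(common, biome_scores$site_id), ]
  grp <- quantile_groups(bs$u_bar, k)
  out <- list()
  for (g in seq_len(k)) {
    sites <- bs$site_id[grp == g]
    if (!length(sites)) {
      out[[g]] <- list(group = g, hsf = NULL, H = NA_real_,
                       se_H = NA_real_, n_sites = 0L, empty = TRUE)
      next
    }
    agg <- aggregate_hsf(hsf_per_site[sites], n_max = n_max)
    agg$sparse <- agg$n_records < sparse_threshold
    H <- se <- NA_real_
    usable <- sum(agg$scale_yr >= band_H[1] & agg$scale_yr <= band_H[2] &
                    agg$S > 0)
    if (usable >= 3) {
      f <- fit_H(agg, band_H)
      H <- f$H; se <- f$se_H
    }
    out[[g]] <- list(group = g, hsf = agg, H = H, se_H = se,
                     n_sites = length(sites), empty = FALSE)
  }
  out
}
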