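#' Construct a pollen record
#'
#' One site's dated pollen count matrix plus coordinates and metadata.
#' Samples are rows (ascending age in calendar years BP, present = 1950
#' CE, post-1950 ages negative), taxa are columns.
#'
#' @param site_id character site identifier
#' @param lat,lon decimal degrees; `abs(lat) <= 90`
#' @param times sample ages in years BP, strictly increasing
#' @param taxa character vector of harmonized taxon names
#' @param counts n x p matrix of nonnegative counts; every row must have
#'   a positive total
#' @param class_labels optional named list of class labels (e.g.
#'   `olson_class`, `cci_class`)
#' @return object of class `pollen_record` with a derived `region` label
#'   ("N_America" for lon in [-170, -30), "W_Eurasia" for lon < 60 E,
#'   "E_Eurasia" otherwise)
#' @export
pollen_record <- function(site_id, lat, lon, times, taxa, counts,
                          class_labels = NULL) {
  counts <- as.matrix(counts)
  if (length(times) != nrow(counts)) stop("length(times) must equal nrow(counts)")
  if (length(taxa) != ncol(counts)) stop("length(taxa) must equal ncol(counts)")
  if (nrow(counts) < 1) stop("a record needs at least one sample")
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing")
  if (abs(lat) > 90) stop("`lat` must be within [-90, 90]")
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (any(rowSums(counts) <= 0)) {
    bad <- times[rowSums(counts) <= 0]
    stop("every sample needs a positive total count; zero at age(s) ",
         paste(bad, collapse = ", "))
  }
  colnames(counts) <- taxa
  structure(
    list(site_id = as.character(site_id), lat = lat, lon = lon,
         times = as.numeric(times), taxa = as.character(taxa),
         counts = counts, class_labels = class_labels,
         region = derive_region(lon)),
    class = "pollen_record"
  )
}

#' @export
print.pollen_record <- function(x, ...) {
  cat(sprintf("pollen_record '%s' (%.2f, %.2f; %s): %d samples x %d taxa, %s-%s yr BP\n",
              x$site_id, x$lat, x$lon, x$region, nrow(x$counts),
              ncol(x$counts), format(min(x$times)), format(max(x$times))))
  invisible(x)
}

# longitudinal region convention: the Americas, then Eurasia split at 60 E
derive_region <- function(lon) {
  if (lon >= -170 && lon < -30) "N_America"
  else if (lon < 60) "W_Eurasia"
  else "E_Eurasia"
}

#' Load pollen records from long-format CSV tables
#'
#' @param counts_path CSV with columns `site_id, age_bp, taxon, count`
#' @param meta_path CSV with columns `site_id, lat, lon` plus optional
#'   class-label columns (e.g. `class`, `olson_class`, `cci_class`)
#' @param taxon_map optional named character vector mapping synonym
#'   taxon names to harmonized ones; counts of synonyms are summed
#' @return named list of [pollen_record()]s, one per site
#' @details Duplicate (site, age, taxon) rows are summed with a warning.
#'   A site present in the counts table but absent from the metadata is
#'   an error.
#' @export
load_records <- function(counts_path, meta_path, taxon_map = NULL) {
  counts <- utils::read.csv(counts_path, stringsAsFactors = FALSE)
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  need_c <- c("site_id", "age_bp", "taxon", "count")
  miss <- setdiff(need_c, names(counts))
  if (length(miss)) stop("counts table missing column(s): ", paste(miss, collapse = ", "))
  need_m <- c("site_id", "lat", "lon")
  miss <- setdiff(need_m, names(meta))
  if (length(miss)) stop("metadata table missing column(s): ", paste(miss, collapse = ", "))

  orphan <- setdiff(unique(counts$site_id), meta$site_id)
  if (length(orphan)) {
    stop("site(s) in counts but not in metadata: ", paste(orphan, collapse = ", "))
  }

  if (!is.null(taxon_map)) {
    hit <- counts$taxon %in% names(taxon_map)
    counts$taxon[hit] <- unname(taxon_map[counts$taxon[hit]])
  }

  dup <- duplicated(counts[, c("site_id", "age_bp", "taxon")])
  if (any(dup)) {
    warning(sum(dup), " duplicate (site, age, taxon) row(s) summed")
  }
  agg <- stats::aggregate(count ~ site_id + age_bp + taxon, data = counts, FUN = sum)

  class_cols <- setdiff(names(meta), need_m)
  out <- list()
  for (sid in unique(agg$site_id)) {
    sub <- agg[agg$site_id == sid, ]
    wide <- stats::xtabs(count ~ age_bp + taxon, data = sub)
    times <- as.numeric(rownames(wide))
    m <- matrix(as.numeric(wide), nrow(wide), ncol(wide),
                dimnames = list(NULL, colnames(wide)))
    mrow <- meta[match(sid, meta$site_id), ]
    labels <- if (length(class_cols)) as.list(mrow[class_cols]) else NULL
    out[[sid]] <- pollen_record(site_id = sid, lat = mrow$lat, lon = mrow$lon,
                                times = times, taxa = colnames(m), counts = m,
                                class_labels = labels)
  }
  out
}

#' Write pollen records to long-format CSV tables
#'
#' Emits the same schema consumed by [load_records()], so synthetic and
#' real data are interchangeable. Zero counts are omitted from the long
#' table.
#'
#' @param records list of [pollen_record()]
#' @param counts_path,meta_path output CSV paths
#' @return invisibly, the long-format counts data.frame
#' @export
write_records <- function(records, counts_path, meta_path) {
  long <- do.call(rbind, lapply(records, function(r) {
    idx <- which(r$counts > 0, arr.ind = TRUE)
    data.frame(site_id = r$site_id, age_bp = r$times[idx[, 1]],
               taxon = r$taxa[idx[, 2]],
               count = r$counts[idx], stringsAsFactors = FALSE)
  }))
  meta <- do.call(rbind, lapply(records, function(r) {
    base <- data.frame(site_id = r$site_id, lat = r$lat, lon = r$lon,
                       stringsAsFactors = FALSE)
    if (!is.null(r$class_labels)) base <- cbind(base, as.data.frame(r$class_labels))
    base
  }))
  utils::write.csv(long, counts_path, row.names = FALSE)
  utils::write.csv(meta, meta_path, row.names = FALSE)
  invisible(long)
}

#' Convert counts to an assemblage matrix of proportions
#'
#' Divides each sample's taxon counts by its total, so rows sum to 1.
#'
#' @param record a [pollen_record()]
#' @return object of class `assemblage_matrix`: the n x p matrix with
#'   attribute `transform_state = "proportion"`
#' @export
to_proportions <- function(record) {
  tot <- rowSums(record$counts)
  if (any(tot <= 0)) {
    stop("zero-total sample at age(s) ",
         paste(record$times[tot <= 0], collapse = ", "))
  }
  m <- record$counts / tot
  structure(m, transform_state = "proportion", class = c("assemblage_matrix", "matrix"))
}

#' Square-root transform an assemblage matrix
#'
#' The square root of proportions (a Hellinger-style transform) damps
#' dominant taxa and raises the contribution of less frequent ones
#' before ordination; squared row sums remain 1.
#'
#' @param assemblage an `assemblage_matrix` in `proportion` state
#' @return the element-wise square root, `transform_state = "sqrt_proportion"`
#' @export
sqrt_transform <- function(assemblage) {
  state <- attr(assemblage, "transform_state")
  if (identical(state, "sqrt_proportion")) {
    stop("assemblage is already square-root transformed")
  }
  if (!identical(state, "proportion")) {
    stop("`assemblage` must be an assemblage_matrix in 'proportion' state")
  }
  structure(sqrt(unclass(assemblage)), transform_state = "sqrt_proportion",
            class = c("assemblage_matrix", "matrix"))
}

#' Filter records by analysis window, sample count and latitude
#'
#' Samples outside the analysis window are dropped first; records with
#' fewer than `min_samples` remaining samples, or located at or south of
#' `min_lat`, are then removed. Filtering is idempotent.
#'
#' @param records list of [pollen_record()]
#' @param min_samples minimum number of in-window samples (default 6)
#' @param min_lat minimum latitude in degrees north (default 25; strict:
#'   a record needs `lat > min_lat`)
#' @param window analysis window in years BP, closed on both ends
#'   (default `c(2000, 8000)`)
#' @return filtered list; attribute `filter_report` counts removals per
#'   rule (`n_input`, `removed_lat`, `removed_samples`, `n_retained`)
#' @export
filter_records <- function(records, min_samples = 6, min_lat = 25,
                           window = c(2000, 8000)) {
  n_in <- length(records)
  removed_lat <- 0L; removed_samples <- 0L
  kept <- list()
  for (r in records) {
    if (r$lat <= min_lat) { removed_lat <- removed_lat + 1L; next }
    sel <- r$times >= window[1] & r$times <= window[2]
    if (sum(sel) < min_samples) { removed_samples <- removed_samples + 1L; next }
    trimmed <- pollen_record(r$site_id, r$lat, r$lon, r$times[sel],
                             r$taxa, r$counts[sel, , drop = FALSE],
                             r$class_labels)
    kept[[r$site_id]] <- trimmed
  }
  structure(kept, filter_report = list(
    n_input = n_in, removed_lat = removed_lat,
    removed_samples = removed_samples, n_retained = length(kept)
  ))
}

#' Align vectors or matrices onto a shared taxon union
#'
#' Taxa absent from an input become zero-filled columns, so records with
#' different taxon lists can be compared.
#'
#' @param ... named numeric vectors (taxa as names) or matrices with
#'   taxa as column names
#' @return list of inputs expanded onto the sorted union of taxa
#' @export
align_taxa <- function(...) {
  xs <- list(...)
  get_taxa <- function(x) if (is.matrix(x)) colnames(x) else names(x)
  union_taxa <- sort(unique(unlist(lapply(xs, get_taxa))))
  lapply(xs, function(x) {
    if (is.matrix(x)) {
      out <- matrix(0, nrow(x), length(union_taxa),
                    dimnames = list(rownames(x), union_taxa))
      out[, colnames(x)] <- x
    } else {
      out <- stats::setNames(numeric(length(union_taxa)), union_taxa)
      out[names(x)] <- x
    }
    out
  })
}
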