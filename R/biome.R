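#' Per-record mean recent assemblage
#'
#' For every record with at least one sample dated to the recent window
#' (default 500 yr BP to the present, post-1950 ages negative), averages
#' the sample proportion rows over the window and square-roots the
#' result. Records without recent samples are excluded.
#'
#' The within-record average is taken on proportions and the square root
#' applied afterwards (`order = "mean_then_sqrt"`); set
#' `order = "sqrt_then_mean"` to average already square-rooted rows.
#'
#' @param records list of [pollen_record()]
#' @param window recent window in years BP (default `c(-60, 500)`)
#' @param order `"mean_then_sqrt"` (default) or `"sqrt_then_mean"`
#' @return named list (by site_id) of named numeric vectors of
#'   square-rooted mean proportions; each carries attribute `class_labels`
#' @export
recent_assemblages <- function(records, window = c(-60, 500),
                               order = c("mean_then_sqrt", "sqrt_then_mean")) {
  order <- match.arg(order)
  out <- list()
  for (r in records) {
    sel <- r$times >= window[1] & r$times <= window[2]
    if (!any(sel)) next
    props <- unclass(to_proportions(r))[sel, , drop = FALSE]
    a <- switch(order,
                mean_then_sqrt = sqrt(colMeans(props)),
                sqrt_then_mean = colMeans(sqrt(props)))
    names(a) <- r$taxa
    attr(a, "class_labels") <- r$class_labels
    out[[r$site_id]] <- a
  }
  out
}

#' Typical assemblage of a biome
#'
#' The typical assemblage of a biome is the mean square-rooted
#' assemblage of the recent samples whose sites belong to the biome's
#' intersection classes. When `group_weights` is given (e.g. to give
#' boreal evergreen and boreal deciduous surface sets equal say despite
#' unequal record counts), the mean is taken per group first and the
#' group means combined with the stated weights regardless of group
#' sizes.
#'
#' @param recent_set output of [recent_assemblages()]
#' @param class_selection character vector of class labels to include;
#'   matched against each record's `class` label
#' @param group_weights optional named numeric vector (class -> weight);
#'   weights are renormalized to sum to 1
#' @param biome_id identifier stored on the result
#' @return object of class `typical_assemblage`: list with `biome_id`,
#'   `taxa`, `weights` (mean sqrt-proportions on the taxon union),
#'   `n_source_records`, `class_selection`
#' @export
typical_assemblage <- function(recent_set, class_selection,
                               group_weights = NULL, biome_id = NA_character_) {
  get_class <- function(a) {
    cl <- attr(a, "class_labels")
    if (is.null(cl)) NA_character_ else as.character(cl$class %||% cl[[1]])
  }
  classes <- vapply(recent_set, get_class, character(1))
  sel <- which(classes %in% class_selection)
  if (!length(sel)) {
    stop("no recent assemblage in class(es): ",
         paste(class_selection, collapse = ", "))
  }
  aligned <- do.call(align_taxa, unname(recent_set[sel]))
  mat <- do.call(rbind, aligned)
  if (is.null(group_weights)) {
    wts <- colMeans(mat)
  } else {
    gw <- group_weights / sum(group_weights)
    grp_means <- lapply(names(gw), function(g) {
      rows <- which(classes[sel] == g)
      if (!length(rows)) stop("no recent assemblage in weighted group: ", g)
      colMeans(mat[rows, , drop = FALSE])
    })
    wts <- Reduce(`+`, Map(`*`, grp_means, gw))
  }
  structure(
    list(biome_id = biome_id, taxa = colnames(mat), weights = wts,
         n_source_records = length(sel), class_selection = class_selection),
    class = "typical_assemblage"
  )
}

#' Difference axis between two typical assemblages
#'
#' The element-wise difference `a_i - a_j` on the union of the two taxon
#' lists (zero fill). Taxa equally dominant in both biomes cancel, so
#' the axis is carried by the taxa that discriminate them; projecting a
#' fossil sample onto it gives a score whose sign indicates proximity to
#' biome i (positive) or biome j (negative).
#'
#' @param a_i,a_j `typical_assemblage` objects
#' @return object of class `difference_axis`: list with `axis_id`
#'   ("i,j", orientation positive toward i), `taxa`, `values`
#' @export
difference_axis <- function(a_i, a_j) {
  al <- align_taxa(a_i$weights, a_j$weights)
  structure(
    list(axis_id = paste(a_i$biome_id, a_j$biome_id, sep = ","),
         taxa = names(al[[1]]), values = al[[1]] - al[[2]]),
    class = "difference_axis"
  )
}

#' Taxa dominating a difference axis
#'
#' @param axis a `difference_axis`
#' @param threshold minimum absolute contribution to display (default 0.05)
#' @return data.frame of `taxon`, `value`, ascending by value
#' @export
axis_top_taxa <- function(axis, threshold = 0.05) {
  sel <- abs(axis$values) > threshold
  d <- data.frame(taxon = axis$taxa[sel], value = unname(axis$values[sel]))
  d[order(d$value), ]
}

#' Project a record onto a difference axis
#'
#' Per sample, the score is the uncentred dot product of the sample's
#' square-rooted proportions with the axis values on the taxon union
#' (zero fill). The projection is deliberately uncentred: the sign of
#' the score at zero carries the biome identity, which column centring
#' would destroy.
#'
#' @param record a [pollen_record()]
#' @param axis a `difference_axis`
#' @return list of class `score_series`: `times`, `values`,
#'   `source = axis_id`
#' @export
project_scores <- function(record, axis) {
  if (!length(intersect(record$taxa, axis$taxa))) {
    stop("no shared taxa between record '", record$site_id, "' and axis ",
         axis$axis_id)
  }
  sq <- sqrt_transform(to_proportions(record))
  al <- align_taxa(unclass(sq), axis$values)
  scores <- as.numeric(al[[1]] %*% al[[2]])
  structure(
    list(times = record$times, values = scores, source = axis$axis_id),
    class = "score_series"
  )
}

#' Mean biome score over the analysis window
#'
#' @param score_series a `score_series` from [project_scores()]
#' @param window analysis window in years BP, closed (default
#'   `c(2000, 8000)`)
#' @return list with `u_bar` (NA when no sample falls in the window) and
#'   `n_samples_in_window`
#' @export
mean_score <- function(score_series, window = c(2000, 8000)) {
  sel <- score_series$times >= window[1] & score_series$times <= window[2]
  list(u_bar = if (any(sel)) mean(score_series$values[sel]) else NA_real_,
       n_samples_in_window = sum(sel))
}

#' Equal-count quantile groups of mean biome scores
#'
#' Rank-based bins with group sizes differing by at most one (remainder
#' sites go to the lowest groups); ties are broken by stable input
#' order. Group 1 holds the lowest scores.
#'
#' @param u_bar numeric vector of mean scores
#' @param k number of groups (default 5, i.e. 20% quantiles)
#' @return integer vector of group labels `1..k`, same order as input
#' @export
quantile_groups <- function(u_bar, k = 5) {
  n <- length(u_bar)
  if (n < k) stop("fewer sites (", n, ") than groups (", k, ")")
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  grp_sorted <- rep(seq_len(k), times = sizes)
  out <- integer(n)
  out[order(u_bar)] <- grp_sorted   # order() is stable: ties keep input order
  out
}

#' Binary site selection for the iterative biome chain
#'
#' Selection rules used to iterate the comparative analysis: keep sites
#' on the positive side of an axis (`positive`), keep the top fraction
#' by score (`upper_q`), or keep sites of one longitudinal region
#' (`region`). Sites with `u_bar == 0` fall to the negative side (a
#' message notes them).
#'
#' @param biome_scores data.frame with columns `site_id`, `u_bar`, and
#'   (for the region rule) `region`
#' @param rule one of `rule_positive()`, `rule_upper_q(fraction)`,
#'   `rule_region(label)`
#' @return character vector of selected site_ids
#' @export
binary_filter <- function(biome_scores, rule) {
  if (!is.list(rule) || is.null(rule$type)) stop("unknown rule")
  switch(rule$type,
    positive = {
      if (any(biome_scores$u_bar == 0, na.rm = TRUE)) {
        message("site(s) with u_bar == 0 assigned to the negative side")
      }
      biome_scores$site_id[!is.na(biome_scores$u_bar) & biome_scores$u_bar > 0]
    },
    upper_q = {
      ok <- !is.na(biome_scores$u_bar)
      n_keep <- round(rule$fraction * sum(ok))
      ord <- order(biome_scores$u_bar[ok], decreasing = TRUE)
      biome_scores$site_id[ok][ord[seq_len(n_keep)]]
    },
    region = {
      biome_scores$site_id[biome_scores$region == rule$label]
    },
    stop("unknown rule type: ", rule$type)
  )
}

#' @rdname binary_filter
#' @export
rule_positive <- function() list(type = "positive")

#' @rdname binary_filter
#' @param fraction fraction of sites to keep (e.g. 0.4 for the upper 40%
#'   quantile)
#' @export
rule_upper_q <- function(fraction) list(type = "upper_q", fraction = fraction)

#' @rdname binary_filter
#' @param label region label (e.g. `"W_Eurasia"`)
#' @export
rule_region <- function(label) list(type = "region", label = label)
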