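#' Principal component analysis of a square-rooted assemblage
#'
#' Eigendecomposition of the column-centred covariance matrix of the
#' square-rooted proportions (no column standardization). The PC1 score
#' time series summarizes the locally dominant component of
#' compositional variability in one record.
#'
#' Sign convention: each eigenvector is oriented so that its
#' largest-magnitude loading is positive. This is deterministic and
#' record-local; downstream Haar analysis is sign-invariant.
#'
#' @param sqrt_assemblage an `assemblage_matrix` in `sqrt_proportion`
#'   state (or any numeric matrix of sample rows)
#' @param k number of components to retain (default: all)
#' @return object of class `pca_result`: list with `eigenvalues`
#'   (descending), `loadings` (p x k, unit-norm columns), `scores`
#'   (n x k), `explained_fraction`
#' @export
pca_pc1 <- function(sqrt_assemblage, k = NULL) {
  x <- unclass(sqrt_assemblage)
  if (nrow(x) < 3) stop("need at least 3 samples for PCA")
  centred <- scale(x, center = TRUE, scale = FALSE)
  total_var <- sum(apply(x, 2L, stats::var))
  if (total_var <= .Machine$double.eps * ncol(x)) {
    stop("degenerate input: assemblage has zero total variance")
  }
  if (sum(apply(x, 2L, stats::var) > 0) < 2) {
    stop("need at least 2 taxa with nonzero variance")
  }
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  eig <- p$sdev^2
  k <- k %||% length(eig)
  k <- min(k, length(eig))
  load <- p$rotation[, seq_len(k), drop = FALSE]
  scores <- p$x[, seq_len(k), drop = FALSE]
  # orient: largest-|loading| entry positive
  for (j in seq_len(k)) {
    imax <- which.max(abs(load[, j]))
    if (load[imax, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(
    list(eigenvalues = eig, loadings = load, scores = scores,
         explained_fraction = eig / sum(eig)),
    class = "pca_result"
  )
}

#' Extract the PC1 score series of a record
#'
#' @param record a [pollen_record()]
#' @return list of class `score_series`: `times`, `values` (PC1 scores),
#'   `source = "PC1"`, plus `explained_fraction_pc1`
#' @export
pc1_scores <- function(record) {
  sq <- sqrt_transform(to_proportions(record))
  p <- pca_pc1(sq, k = 1)
  structure(
    list(times = record$times, values = p$scores[, 1], source = "PC1",
         explained_fraction_pc1 = p$explained_fraction[1]),
    class = "score_series"
  )
}

#' Taxon best correlated with the PC1 score series
#'
#' Finds the assemblage column maximizing the squared Pearson
#' correlation with the PC1 scores. Zero-variance columns are skipped;
#' ties go to the first column in order (with a message).
#'
#' @param pca_result a `pca_result` from [pca_pc1()]
#' @param sqrt_assemblage the matrix the PCA was computed on
#' @return list with `taxon` and `r2`
#' @export
best_correlated_taxon <- function(pca_result, sqrt_assemblage) {
  x <- unclass(sqrt_assemblage)
  pc1 <- pca_result$scores[, 1]
  v <- apply(x, 2L, stats::var)
  usable <- which(v > 0)
  if (!length(usable)) stop("no taxon with nonzero variance")
  r2 <- vapply(usable, function(j) stats::cor(x[, j], pc1)^2, numeric(1))
  best <- which(r2 >= max(r2) - 1e-12)
  if (length(best) > 1) {
    message("tie among taxa (", paste(colnames(x)[usable[best]], collapse = ", "),
            "); keeping the first by column order")
  }
  j <- usable[best[1]]
  list(taxon = colnames(x)[j] %||% paste0("taxon_", j), r2 = unname(r2[best[1]]))
}
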