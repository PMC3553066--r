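#' Filter and impute missing values in an expression matrix
#'
#' Two-stage preprocessing of an expression matrix that may contain missing
#' entries: (1) features, then samples, with more than `missing_fraction`
#' missing values are removed (one pass each, features first); (2) every
#' remaining missing value is imputed by k-nearest-neighbour averaging over
#' features.
#'
#' For a missing cell (f, s), candidate neighbours are the features observed
#' in sample s; the distance between features is the root-mean-square
#' difference over the samples observed in both (so features sharing fewer
#' samples are not artificially close), and the imputed value is the mean of
#' the `k_neighbours` nearest candidates' values in sample s. Distance ties
#' are broken by feature order, so the result is deterministic.
#'
#' @param x a [expression_matrix()] object, possibly with `NA` entries.
#' @param missing_fraction maximum tolerated fraction of missing values per
#'   feature / per sample (default 0.4).
#' @param k_neighbours number of nearest features to average (default 10).
#' @return A fully observed `copa_matrix` (with `n_normal` adjusted if
#'   normal columns were removed).
#' @export
preprocess <- function(x, missing_fraction = 0.4, k_neighbours = 10) {
  stopifnot(inherits(x, "copa_matrix"))
  if (missing_fraction <= 0 || missing_fraction > 1)
    stop("'missing_fraction' must be in (0, 1]")
  k_neighbours <- as.integer(k_neighbours)
  if (k_neighbours < 1L) stop("'k_neighbours' must be >= 1")

  v <- x$values
  is_normal <- seq_len(ncol(v)) <= x$n_normal

  keep_f <- rowMeans(is.na(v)) <= missing_fraction
  if (!any(keep_f)) stop("empty matrix after filtering")
  v <- v[keep_f, , drop = FALSE]

  keep_s <- colMeans(is.na(v)) <= missing_fraction
  if (sum(keep_s) < 2L) stop("fewer than two samples remain after filtering")
  n_normal <- sum(is_normal[keep_s])
  if (n_normal < 1L) stop("all normal samples removed by missingness filter")
  if (n_normal == sum(keep_s)) stop("all tumour samples removed by missingness filter")
  v <- v[, keep_s, drop = FALSE]

  message(sprintf("preprocess: removed %d/%d features and %d/%d samples (> %.0f%% missing)",
                  sum(!keep_f), length(keep_f), sum(!keep_s), length(keep_s),
                  100 * missing_fraction))

  if (anyNA(v)) {
    if (k_neighbours >= nrow(v)) {
      k_neighbours <- nrow(v) - 1L
      warning("k_neighbours reduced to ", k_neighbours,
              " (must be smaller than the surviving feature count)")
    }
    v <- knn_impute(v, k_neighbours)
  }
  expression_matrix(v, n_normal)
}

#' K-nearest-neighbour imputation over features
#'
#' Workhorse behind [preprocess()]; exported so the imputation step can be
#' applied on its own. See [preprocess()] for the distance and tie-break
#' conventions.
#'
#' @param values numeric matrix (features x samples) with `NA` entries.
#' @param k number of neighbouring features to average.
#' @return The matrix with all `NA` entries replaced.
#' @export
knn_impute <- function(values, k) {
  na_rows <- which(rowSums(is.na(values)) > 0L)
  if (length(na_rows) == 0L) return(values)
  out <- values
  for (f in na_rows) {
    d <- feature_distances(values, f)
    for (s in which(is.na(values[f, ]))) {
      cand <- which(!is.na(values[, s]))
      cand <- cand[is.finite(d[cand])]
      if (length(cand) == 0L) {
        # no usable neighbour: fall back to the sample mean
        out[f, s] <- mean(values[, s], na.rm = TRUE)
        next
      }
      ord <- cand[order(d[cand], cand)]          # ties by feature order
      nn <- ord[seq_len(min(k, length(ord)))]
      out[f, s] <- mean(values[nn, s])
    }
  }
  out
}

# RMS Euclidean distance from feature f to every feature, over the samples
# observed in both; Inf where no samples are shared (or to itself).
feature_distances <- function(values, f) {
  obs_f <- !is.na(values[f, ])
  d <- rep(Inf, nrow(values))
  for (g in seq_len(nrow(values))) {
    if (g == f) next
    shared <- obs_f & !is.na(values[g, ])
    if (!any(shared)) next
    d[g] <- sqrt(mean((values[f, shared] - values[g, shared])^2))
  }
  d
}
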