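#' Percentile of a sample under a chosen interpolation rule
#'
#' Thin, validated wrapper around the nine classical quantile-interpolation
#' estimators (Hyndman & Fan types 1-9, as implemented by
#' [stats::quantile()]). The package default throughout is type 8, the
#' median-unbiased rule recommended in the quantile-estimation literature.
#'
#' @param values numeric vector, non-empty, no missing values.
#' @param p percentile in `[0, 100]`.
#' @param estimator integer 1-9 selecting the interpolation rule (default 8).
#' @return The p-th percentile; always within `[min(values), max(values)]`.
#' @examples
#' percentile(1:10, 90)           # type 8
#' percentile(1:10, 90, estimator = 7)  # classical linear interpolation
#' @export
percentile <- function(values, p, estimator = 8) {
  if (length(values) == 0L) stop("empty sample")
  if (anyNA(values)) stop("missing values in sample")
  if (length(p) != 1L || is.na(p) || p < 0 || p > 100)
    stop("'p' must be a single value in [0, 100]")
  if (!estimator %in% 1:9) stop("'estimator' must be an integer in 1..9")
  stats::quantile(values, probs = p / 100, type = estimator, names = FALSE)
}

#' COPA transformation: robust per-feature standardisation
#'
#' Centres each feature at its median across *all* samples (normal and
#' tumour) and divides by a robust scale, so that extreme values in a few
#' samples remain visible where mean/SD scaling would absorb them into an
#' inflated standard deviation.
#'
#' Two robust scales are supported: the mean absolute deviation from the
#' median (`"meanad"`, the default — the scale the transform is classically
#' described with) and the median absolute deviation from the median
#' (`"mad"`; un-normalised, i.e. no 1.4826 consistency factor). Outlier
#' *calls* are identical under either choice (fences rescale with the
#' values); only the percentile-separation filter, whose threshold is fixed
#' on the transformed scale, is sensitive to it.
#' Features with zero scale (e.g. constant features) are flagged as
#' degenerate; their transformed values are set to `NA` and they take no
#' part in downstream outlier calling.
#'
#' @param x a [expression_matrix()] object with no missing values.
#' @param scale_mode `"meanad"` or `"mad"`.
#' @return An object of class `copa_transform`: list with `values` (the
#'   transformed matrix), `stats` (data frame with per-feature `centre`,
#'   `scale`, `degenerate`) and `n_normal`.
#' @examples
#' m <- matrix(c(2, 4, 4, 4, 6, 8), 1, 6,
#'             dimnames = list("f1", paste0("s", 1:6)))
#' ct <- copa_transform(expression_matrix(m, 2), scale_mode = "mad")
#' ct$values   # (-2, 0, 0, 0, 2, 4): median 4, MAD 1
#' @export
copa_transform <- function(x, scale_mode = c("meanad", "mad")) {
  stopifnot(inherits(x, "copa_matrix"))
  scale_mode <- match.arg(scale_mode)
  v <- x$values
  if (anyNA(v)) stop("matrix contains missing values; run preprocess() first")

  centre <- apply(v, 1L, stats::median)
  dev <- abs(v - centre)
  scale <- if (scale_mode == "mad") apply(dev, 1L, stats::median) else rowMeans(dev)
  degenerate <- scale == 0

  tv <- (v - centre) / scale
  tv[degenerate, ] <- NA_real_

  if (any(degenerate))
    message(sprintf("copa_transform: %d degenerate feature(s) (zero %s) excluded from calling",
                    sum(degenerate), scale_mode))

  structure(list(
    values = tv,
    stats = data.frame(feature_id = rownames(v), centre = centre, scale = scale,
                       degenerate = degenerate, row.names = NULL,
                       stringsAsFactors = FALSE),
    scale_mode = scale_mode,
    n_normal = x$n_normal
  ), class = "copa_transform")
}

#' @export
print.copa_transform <- function(x, ...) {
  cat(sprintf("copa_transform: %d features x %d samples, scale = %s, %d degenerate\n",
              nrow(x$values), ncol(x$values), x$scale_mode,
              sum(x$stats$degenerate)))
  invisible(x)
}
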