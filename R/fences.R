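#' Outlier-detection parameters
#'
#' Bundles the tunable parameters of the outlier pipeline. The nominated
#' upper/lower percentiles (default 90/10) drive the percentile-separation
#' filter; the fence multiplier (1.5) and the separation threshold (2, in
#' units of the log2 scale) are the method's fixed constants and are exposed
#' only for sensitivity analyses.
#'
#' `c3_scale` selects the scale on which the nominated tumour and normal
#' percentiles are compared in the third filter criterion:
#' `"transformed"` (default) compares percentiles of the COPA-transformed
#' scores, `"raw"` compares percentiles of the pre-transform (log2)
#' expression values. See the package vignette for the rationale.
#'
#' @param upper_percentile nominated upper percentile, in (75, 100].
#' @param lower_percentile nominated lower percentile, in [0, 25).
#' @param fence_multiplier Tukey fence multiplier (default 1.5).
#' @param fc_threshold minimum absolute difference between the nominated
#'   tumour and normal percentile values (default 2).
#' @param estimator quantile-interpolation rule, 1-9 (default 8); used for
#'   every percentile in the pipeline.
#' @param scale_mode robust scale of the COPA transform, `"meanad"`
#'   (default) or `"mad"`.
#' @param c3_scale `"transformed"` or `"raw"`.
#' @return list of class `outlier_params`.
#' @export
outlier_params <- function(upper_percentile = 90, lower_percentile = 10,
                           fence_multiplier = 1.5, fc_threshold = 2,
                           estimator = 8, scale_mode = c("meanad", "mad"),
                           c3_scale = c("transformed", "raw")) {
  scale_mode <- match.arg(scale_mode)
  c3_scale <- match.arg(c3_scale)
  if (!(lower_percentile >= 0 && lower_percentile < 25))
    stop("'lower_percentile' must lie in [0, 25)")
  if (!(upper_percentile > 75 && upper_percentile <= 100))
    stop("'upper_percentile' must lie in (75, 100]")
  if (fence_multiplier <= 0) stop("'fence_multiplier' must be positive")
  if (fc_threshold <= 0) stop("'fc_threshold' must be positive")
  if (!estimator %in% 1:9) stop("'estimator' must be an integer in 1..9")
  structure(list(upper_percentile = upper_percentile,
                 lower_percentile = lower_percentile,
                 fence_multiplier = fence_multiplier,
                 fc_threshold = fc_threshold,
                 estimator = as.integer(estimator),
                 scale_mode = scale_mode,
                 c3_scale = c3_scale),
            class = "outlier_params")
}

#' Per-feature outlier fences and group percentiles
#'
#' From the COPA-transformed values of the tumour samples, computes for each
#' feature the 25th and 75th percentiles, the inter-quartile range, and the
#' Tukey fences `q75 + m * IQR` / `q25 - m * IQR`. The nominated upper and
#' lower percentiles are recorded for tumour and normal groups separately,
#' both on the transformed scale and (when the raw matrix is supplied) on
#' the original expression scale; the percentile-separation filter reads
#' whichever scale `params$c3_scale` selects.
#'
#' Degenerate features (zero robust scale) yield `NA` fences; features whose
#' tumour IQR is zero are flagged `zero_iqr` and are excluded from calling,
#' since a zero-width fence would label any deviation an outlier.
#'
#' @param transformed a [copa_transform()] object.
#' @param params an [outlier_params()] object.
#' @param raw a `copa_matrix` with the pre-transform values (optional; needed
#'   for `c3_scale = "raw"`).
#' @return data frame with one row per feature: `q25_t`, `q75_t`, `iqr_t`,
#'   `upper_fence`, `lower_fence`, `pu_t`, `pl_t`, `pu_n`, `pl_n`,
#'   (`pu_t_raw`, ... when `raw` is given), `degenerate`, `zero_iqr`.
#' @export
compute_fences <- function(transformed, params = outlier_params(), raw = NULL) {
  stopifnot(inherits(transformed, "copa_transform"),
            inherits(params, "outlier_params"))
  v <- transformed$values
  n_normal <- transformed$n_normal
  n_tumour <- ncol(v) - n_normal
  if (n_tumour < 2L) stop("at least 2 tumour samples are required")
  tum <- v[, -seq_len(n_normal), drop = FALSE]
  nor <- v[, seq_len(n_normal), drop = FALSE]
  est <- params$estimator
  pu <- params$upper_percentile
  pl <- params$lower_percentile

  row_pct <- function(m, p) apply(m, 1L, function(r)
    if (anyNA(r)) NA_real_ else percentile(r, p, est))

  q25 <- row_pct(tum, 25)
  q75 <- row_pct(tum, 75)
  iqr <- q75 - q25
  out <- data.frame(
    feature_id = rownames(v),
    q25_t = q25, q75_t = q75, iqr_t = iqr,
    upper_fence = q75 + params$fence_multiplier * iqr,
    lower_fence = q25 - params$fence_multiplier * iqr,
    pu_t = row_pct(tum, pu), pl_t = row_pct(tum, pl),
    pu_n = row_pct(nor, pu), pl_n = row_pct(nor, pl),
    degenerate = transformed$stats$degenerate,
    row.names = NULL, stringsAsFactors = FALSE
  )
  out$zero_iqr <- !out$degenerate & out$iqr_t == 0
  if (any(out$zero_iqr, na.rm = TRUE))
    message(sprintf("compute_fences: %d feature(s) with zero tumour IQR excluded from calling",
                    sum(out$zero_iqr, na.rm = TRUE)))
  if (!is.null(raw)) {
    stopifnot(inherits(raw, "copa_matrix"))
    if (!identical(rownames(raw$values), rownames(v)))
      stop("raw matrix does not match the transformed matrix")
    rt <- raw$values[, -seq_len(n_normal), drop = FALSE]
    rn <- raw$values[, seq_len(n_normal), drop = FALSE]
    out$pu_t_raw <- row_pct(rt, pu)
    out$pl_t_raw <- row_pct(rt, pl)
    out$pu_n_raw <- row_pct(rn, pu)
    out$pl_n_raw <- row_pct(rn, pl)
  }
  out
}
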