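#' Call per-sample outliers against feature-specific fences
#'
#' A (feature, sample) pair is an over-expressed outlier when its
#' COPA-transformed value is strictly greater than the feature's upper
#' fence, and an under-expressed outlier when strictly less than the lower
#' fence; values exactly on a fence are non-outliers. Fences come from the
#' tumour samples but are applied to every sample, so outliers can occur in
#' normal samples too (the filter deals with those). Degenerate and
#' zero-IQR features produce no calls.
#'
#' @param transformed a [copa_transform()] object.
#' @param fences data frame from [compute_fences()] on the same object.
#' @return An object of class `outlier_calls`: list with `codes` (integer
#'   matrix over {1, -1, 0}, features x samples), `excluded` (logical vector
#'   of features excluded from calling) and `n_normal`.
#' @export
call_outliers <- function(transformed, fences) {
  stopifnot(inherits(transformed, "copa_transform"))
  v <- transformed$values
  if (!identical(as.character(fences$feature_id), rownames(v)))
    stop("fences do not match the transformed matrix")
  excluded <- fences$degenerate | fences$zero_iqr
  codes <- matrix(0L, nrow(v), ncol(v), dimnames = dimnames(v))
  ok <- !excluded
  if (any(ok)) {
    up <- v[ok, , drop = FALSE] > fences$upper_fence[ok]
    dn <- v[ok, , drop = FALSE] < fences$lower_fence[ok]
    codes[ok, ][up] <- 1L
    codes[ok, ][dn] <- -1L
  }
  structure(list(codes = codes, excluded = excluded,
                 n_normal = transformed$n_normal),
            class = "outlier_calls")
}

#' Filter outlier calls down to tumour-specific outlier features
#'
#' Applies the method's three retention criteria to one direction at a time.
#' A feature is retained iff:
#' 1. it is an outlier of the given direction in at least one tumour sample;
#' 2. it is not an outlier of the *same* direction in any normal sample
#'    (opposite-direction normal outliers are permitted);
#' 3. the nominated tumour and normal percentile values are separated by
#'    more than `fc_threshold`: for the up direction the nominated upper
#'    percentiles are compared, for the down direction the nominated lower
#'    percentiles, on the scale selected by `params$c3_scale`.
#'
#' @param calls an [call_outliers()] object.
#' @param fences matching data frame from [compute_fences()].
#' @param params the [outlier_params()] used throughout the run.
#' @param direction `"up"` or `"down"`.
#' @return data frame with one row per retained feature: `feature_id`,
#'   `outlier_sample_ids` (comma-joined tumour samples in which the feature
#'   is an outlier), `n_tumour_outliers`, `percentile_tumour`,
#'   `percentile_normal` (on the `c3_scale` scale). The per-criterion
#'   attrition counts are attached as attribute `"attrition"` and the
#'   direction as attribute `"direction"`.
#' @export
filter_outliers <- function(calls, fences, params, direction = c("up", "down")) {
  stopifnot(inherits(calls, "outlier_calls"), inherits(params, "outlier_params"))
  direction <- match.arg(direction)
  code <- if (direction == "up") 1L else -1L
  n_normal <- calls$n_normal
  codes <- calls$codes
  nor <- codes[, seq_len(n_normal), drop = FALSE]
  tum <- codes[, -seq_len(n_normal), drop = FALSE]

  c1 <- rowSums(tum == code) > 0L
  c2 <- rowSums(nor == code) == 0L
  if (params$c3_scale == "raw") {
    if (is.null(fences$pu_t_raw))
      stop("c3_scale = \"raw\" requires fences computed with the raw matrix")
    pt <- if (direction == "up") fences$pu_t_raw else fences$pl_t_raw
    pn <- if (direction == "up") fences$pu_n_raw else fences$pl_n_raw
  } else {
    pt <- if (direction == "up") fences$pu_t else fences$pl_t
    pn <- if (direction == "up") fences$pu_n else fences$pl_n
  }
  c3 <- !is.na(pt) & !is.na(pn) & abs(pt - pn) > params$fc_threshold

  keep <- c1 & c2 & c3
  attrition <- data.frame(
    stage = c("called_in_tumour", "no_normal_same_direction", "percentile_separation"),
    n_in = c(nrow(codes), sum(c1), sum(c1 & c2)),
    n_out = c(sum(c1), sum(c1 & c2), sum(keep)),
    stringsAsFactors = FALSE
  )
  tum_ids <- colnames(tum)
  res <- data.frame(
    feature_id = rownames(codes)[keep],
    outlier_sample_ids = vapply(which(keep), function(f)
      paste(tum_ids[tum[f, ] == code], collapse = ","), character(1L)),
    n_tumour_outliers = rowSums(tum == code)[keep],
    percentile_tumour = pt[keep],
    percentile_normal = pn[keep],
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(res, "attrition") <- attrition
  attr(res, "direction") <- direction
  res
}

#' Run the full outlier-detection pipeline
#'
#' Composition of [copa_transform()], [compute_fences()], [call_outliers()]
#' and [filter_outliers()] in both directions, plus profile construction.
#' The input must already be preprocessed (no missing values); run
#' [preprocess()] first if needed. The result is deterministic for a fixed
#' input and parameter set.
#'
#' @param x a fully observed [expression_matrix()] object.
#' @param params an [outlier_params()] object.
#' @return An object of class `mcopa_result`: list with `up` and `down`
#'   (retained-feature tables, see [filter_outliers()]), `profile` (an
#'   [build_profiles()] code matrix over the retained features), `fences`,
#'   `transform_stats`, `params` and `log` (per-stage feature counts).
#' @examples
#' sim <- generate_expression(simulation_config(n_features = 300, seed = 7))
#' res <- run_mcopa(sim$matrix)
#' res
#' @export
run_mcopa <- function(x, params = outlier_params()) {
  stopifnot(inherits(x, "copa_matrix"))
  if (anyNA(x$values)) stop("matrix contains missing values; run preprocess() first")
  tr <- copa_transform(x, scale_mode = params$scale_mode)
  fe <- compute_fences(tr, params, raw = x)
  ca <- call_outliers(tr, fe)
  up <- filter_outliers(ca, fe, params, "up")
  down <- filter_outliers(ca, fe, params, "down")
  prof <- build_profiles(up, down, sample_ids = colnames(x$values))
  log <- rbind(
    data.frame(direction = "up", attr(up, "attrition"), stringsAsFactors = FALSE),
    data.frame(direction = "down", attr(down, "attrition"), stringsAsFactors = FALSE)
  )
  structure(list(up = up, down = down, profile = prof, fences = fe,
                 transform_stats = tr$stats, params = params, log = log),
            class = "mcopa_result")
}

#' @export
print.mcopa_result <- function(x, ...) {
  cat(sprintf("mcopa_result: %d up-regulated and %d down-regulated outlier features\n",
              nrow(x$up), nrow(x$down)))
  cat(sprintf("  profile: %d features x %d samples\n",
              nrow(x$profile), ncol(x$profile)))
  cat(sprintf("  params: upper %g / lower %g percentile, estimator type %d, scale %s, c3 on %s scale\n",
              x$params$upper_percentile, x$params$lower_percentile,
              x$params$estimator, x$params$scale_mode, x$params$c3_scale))
  invisible(x)
}

#' Write the up/down outlier tables of a result
#'
#' @param result an `mcopa_result`.
#' @param prefix path prefix; writes `<prefix>_up.tsv`, `<prefix>_down.tsv`
#'   and `<prefix>_profile.tsv`.
#' @return character vector of the written paths, invisibly.
#' @export
write_result <- function(result, prefix) {
  stopifnot(inherits(result, "mcopa_result"))
  paths <- c(up = paste0(prefix, "_up.tsv"),
             down = paste0(prefix, "_down.tsv"),
             profile = paste0(prefix, "_profile.tsv"))
  utils::write.table(result$up, paths["up"], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(result$down, paths["down"], sep = "\t", quote = FALSE, row.names = FALSE)
  write_profile(result$profile, paths["profile"])
  invisible(paths)
}
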