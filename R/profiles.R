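#' Build per-feature outlier profiles
#'
#' Merges the up- and down-regulated outlier tables of a run into a single
#' code matrix: one row per feature that survived filtering in at least one
#' direction, one column per sample, with 1 = over-expressed outlier,
#' -1 = under-expressed outlier, 0 = non-outlier. A feature retained in both
#' directions (in different samples) carries both 1 and -1 codes; the same
#' (feature, sample) pair can never carry both, and such an inconsistency in
#' the input tables is an error.
#'
#' @param up,down retained-feature tables from [filter_outliers()] /
#'   [run_mcopa()] over the same samples.
#' @param sample_ids full ordered sample-id vector of the experiment.
#' @return An integer matrix of class `outlier_profile` (features x samples,
#'   values in {1, -1, 0}).
#' @export
build_profiles <- function(up, down, sample_ids) {
  feats <- unique(c(up$feature_id, down$feature_id))
  codes <- matrix(0L, length(feats), length(sample_ids),
                  dimnames = list(feats, sample_ids))
  fill <- function(tab, code) {
    for (i in seq_len(nrow(tab))) {
      s <- split_ids(tab$outlier_sample_ids[i])
      bad <- setdiff(s, sample_ids)
      if (length(bad))
        stop("outlier table references unknown sample(s): ",
             paste(bad, collapse = ", "))
      prev <- codes[tab$feature_id[i], s]
      if (any(prev != 0L & prev != code))
        stop("conflicting up/down call for feature ", tab$feature_id[i])
      codes[tab$feature_id[i], s] <<- code
    }
  }
  fill(up, 1L)
  fill(down, -1L)
  structure(codes, class = c("outlier_profile", class(codes)))
}

split_ids <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, ",", fixed = TRUE)[[1L]]
}

#' Extract features that are outliers in a given sample set
#'
#' The profile-level analogue of asking "which features mark this subtype":
#' with `exclusive = TRUE` (default) a feature is returned when *all* of its
#' outlier codes of the requested direction fall inside the selection (and
#' at least one does); with `exclusive = FALSE` one such code inside the
#' selection suffices.
#'
#' @param profile an [build_profiles()] code matrix.
#' @param samples character vector of selected sample ids (e.g. a cluster).
#' @param direction `"both"` (default; any nonzero code), `"up"` or
#'   `"down"`.
#' @param exclusive logical; see above.
#' @return character vector of feature ids.
#' @export
subtype_outliers <- function(profile, samples,
                             direction = c("both", "up", "down"),
                             exclusive = TRUE) {
  direction <- match.arg(direction)
  unknown <- setdiff(samples, colnames(profile))
  if (length(unknown))
    stop("unknown sample id(s): ", paste(unknown, collapse = ", "))
  if (length(samples) == 0L) stop("empty sample selection")
  m <- switch(direction,
              both = profile != 0L,
              up = profile == 1L,
              down = profile == -1L)
  inside <- rowSums(m[, samples, drop = FALSE]) > 0L
  outside <- rowSums(m[, setdiff(colnames(profile), samples), drop = FALSE]) > 0L
  keep <- if (exclusive) inside & !outside else inside
  rownames(profile)[keep]
}

#' Per-sample outlier feature lists
#'
#' Inverts a profile: for every sample, the features in which it is an over-
#' or under-expressed outlier.
#'
#' @param profile an [build_profiles()] code matrix.
#' @return named list (one element per sample) of lists with character
#'   vectors `up` and `down`.
#' @export
sample_outlier_lists <- function(profile) {
  out <- lapply(colnames(profile), function(s)
    list(up = rownames(profile)[profile[, s] == 1L],
         down = rownames(profile)[profile[, s] == -1L]))
  stats::setNames(out, colnames(profile))
}

#' How many selected samples share each outlier feature
#'
#' For the features with at least one outlier code inside the selection,
#' counts in how many selected samples each is an outlier and tabulates the
#' result; features whose outlier codes fall only outside the selection are
#' counted separately (the `outside` element).
#'
#' @param profile an [build_profiles()] code matrix.
#' @param samples selected sample ids (e.g. a metastatic cluster).
#' @param direction `"both"`, `"up"` or `"down"`.
#' @return list with `histogram` (named integer vector: number of features
#'   shared by k = 1, 2, ... selected samples) and `outside` (count of
#'   features with outlier codes only outside the selection).
#' @export
sharing_histogram <- function(profile, samples,
                              direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  unknown <- setdiff(samples, colnames(profile))
  if (length(unknown))
    stop("unknown sample id(s): ", paste(unknown, collapse = ", "))
  m <- switch(direction,
              both = profile != 0L,
              up = profile == 1L,
              down = profile == -1L)
  k_inside <- rowSums(m[, samples, drop = FALSE])
  any_outside <- rowSums(m[, setdiff(colnames(profile), samples), drop = FALSE]) > 0L
  inside <- k_inside > 0L
  hist <- table(factor(k_inside[inside],
                       levels = seq_len(max(1L, length(samples)))))
  list(histogram = stats::setNames(as.integer(hist), names(hist)),
       outside = sum(!inside & any_outside))
}

#' Write / read an outlier profile as tab-separated text
#'
#' First column `feature_id`, then one column per sample holding 1, -1 or 0.
#'
#' @param profile an [build_profiles()] code matrix.
#' @param path file path.
#' @return `write_profile()` returns `path` invisibly; `read_profile()`
#'   returns an `outlier_profile` matrix.
#' @export
write_profile <- function(profile, path) {
  d <- data.frame(feature_id = rownames(profile), profile,
                  check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  d <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                         stringsAsFactors = FALSE, quote = "")
  m <- as.matrix(d[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  if (!all(m %in% c(-1L, 0L, 1L))) stop("profile codes must be 1, -1 or 0")
  rownames(m) <- as.character(d[[1L]])
  structure(m, class = c("outlier_profile", class(m)))
}
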