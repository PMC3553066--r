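#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two partitions of the same samples,
#' computed from the pair counts of the cluster contingency table:
#' `(Index - ExpectedIndex) / (MaximumIndex - ExpectedIndex)` where
#' `Index = sum_ij C(n_ij, 2)`, `ExpectedIndex = sum_i C(n_i, 2) *
#' sum_j C(n_j, 2) / C(n, 2)` and `MaximumIndex = (sum_i C(n_i, 2) +
#' sum_j C(n_j, 2)) / 2`. Identical partitions score 1; the expectation
#' under random relabelling with fixed cluster sizes is exactly 0; negative
#' values indicate less agreement than chance.
#'
#' When both partitions put every sample in one cluster, or every sample in
#' its own cluster, the denominator is 0; by convention the result is then
#' 1 if the partitions are identical and 0 otherwise.
#'
#' @param k,l cluster label vectors over the same samples (any label type).
#'   If both are named, they are aligned by name and the sample sets must
#'   match.
#' @return A single number, at most 1.
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2))  # -0.5
#' @export
adjusted_rand_index <- function(k, l) {
  if (!is.null(names(k)) && !is.null(names(l))) {
    if (!setequal(names(k), names(l)))
      stop("partitions cover different sample sets")
    l <- l[names(k)]
  }
  if (length(k) != length(l))
    stop("partitions have different lengths")
  tab <- table(k, l)
  n <- sum(tab)
  idx <- sum(choose(tab, 2))
  a <- sum(choose(rowSums(tab), 2))
  b <- sum(choose(colSums(tab), 2))
  expected <- a * b / choose(n, 2)
  maximum <- (a + b) / 2
  if (maximum == expected) {
    identical_partition <- all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
    return(if (identical_partition) 1 else 0)
  }
  (idx - expected) / (maximum - expected)
}

#' Feature selection by expression variance
#'
#' Ranks features by their sample variance across all samples and returns
#' the top `k`, ties broken by feature order.
#'
#' @param x a [expression_matrix()] object.
#' @param k number of features to select (default 1000, capped at the
#'   feature count).
#' @return list of class `selection_result` with `method`, `features`
#'   (selected ids, descending score) and `scores` (named, all features).
#' @export
variance_select <- function(x, k = 1000) {
  stopifnot(inherits(x, "copa_matrix"))
  scores <- apply(x$values, 1L, stats::var)
  k <- min(k, length(scores))
  ord <- order(-scores)                     # stable: ties by feature order
  selection_result("variance", rownames(x$values)[ord][seq_len(k)], scores)
}

#' Feature selection by COPA percentile ranking
#'
#' The original COPA selector: features are ranked (descending) by the
#' nominated percentile of their COPA-transformed tumour values and the top
#' `k` are returned — an over-expression ranking with no outlier filtering.
#' Degenerate features rank last.
#'
#' @param x a [expression_matrix()] object.
#' @param k number of features to select.
#' @param pct ranking percentile (default 90).
#' @param params [outlier_params()] supplying the estimator and scale mode.
#' @return a `selection_result` (see [variance_select()]).
#' @export
copa_rank_select <- function(x, k, pct = 90, params = outlier_params()) {
  stopifnot(inherits(x, "copa_matrix"))
  tr <- copa_transform(x, scale_mode = params$scale_mode)
  tum <- tr$values[, -seq_len(tr$n_normal), drop = FALSE]
  scores <- apply(tum, 1L, function(r)
    if (anyNA(r)) -Inf else percentile(r, pct, params$estimator))
  k <- min(k, length(scores))
  ord <- order(-scores)
  selection_result("copa", rownames(x$values)[ord][seq_len(k)], scores)
}

#' Feature selection by differential expression (Welch t + BH)
#'
#' A simple differential-expression comparator: per-feature two-sample
#' Welch t-test of normal versus tumour means, Benjamini-Hochberg adjustment
#' across features, and selection of the features with adjusted p below
#' `alpha`. Features with zero variance in both groups and identical means
#' get p = 1. This is a deliberately plain comparator (no variance
#' moderation); its role here is relative benchmarking of selectors.
#'
#' @param x a [expression_matrix()] object with at least 2 samples per group.
#' @param alpha adjusted-p threshold (default 0.01).
#' @return a `selection_result`; `scores` are `1 - adjusted p` so that
#'   larger means more significant, and the adjusted p-values themselves are
#'   attached as `adjusted_p`.
#' @export
de_select <- function(x, alpha = 0.01) {
  stopifnot(inherits(x, "copa_matrix"))
  n1 <- x$n_normal
  n2 <- ncol(x$values) - n1
  if (n1 < 2L || n2 < 2L) stop("at least 2 samples per group are required")
  g1 <- x$values[, seq_len(n1), drop = FALSE]
  g2 <- x$values[, -seq_len(n1), drop = FALSE]
  m1 <- rowMeans(g1); m2 <- rowMeans(g2)
  v1 <- apply(g1, 1L, stats::var); v2 <- apply(g2, 1L, stats::var)
  se2 <- v1 / n1 + v2 / n2
  p <- ifelse(se2 == 0,
              ifelse(m1 == m2, 1, 0),
              {
                t <- (m2 - m1) / sqrt(se2)
                df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
                2 * stats::pt(-abs(t), df)
              })
  padj <- stats::p.adjust(p, method = "BH")
  names(padj) <- rownames(x$values)
  sel <- rownames(x$values)[padj < alpha]
  sel <- sel[order(padj[sel])]
  res <- selection_result("de", sel, 1 - padj)
  res$adjusted_p <- padj
  res
}

selection_result <- function(method, features, scores) {
  structure(list(method = method, features = features, scores = scores),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection_result (%s): %d features selected of %d\n",
              x$method, length(x$features), length(x$scores)))
  invisible(x)
}

#' Cluster samples on a feature subset
#'
#' Partitions samples (columns) with k-means or PAM on Euclidean distance
#' over the supplied features. K-means uses the MacQueen algorithm and keeps
#' the best of `n_repeats` seeded starts by total within-cluster sum of
#' squares; given a seed, both methods are deterministic.
#'
#' @param values numeric matrix, features x samples (typically a selected
#'   subset of rows of an expression matrix).
#' @param method `"kmeans"` or `"pam"`.
#' @param n_clusters number of clusters, 2..number of samples.
#' @param n_repeats k-means restarts (default 20; ignored by PAM).
#' @param seed integer seed for the k-means starts (optional).
#' @return named integer vector of cluster labels, one per sample.
#' @export
cluster_samples <- function(values, method = c("kmeans", "pam"), n_clusters,
                            n_repeats = 20, seed = NULL) {
  method <- match.arg(method)
  if (n_clusters < 2L || n_clusters > ncol(values))
    stop("'n_clusters' must be between 2 and the number of samples")
  m <- t(values)
  if (method == "kmeans") {
    labels <- with_seed(seed, stats::kmeans(
      m, centers = n_clusters, algorithm = "MacQueen",
      nstart = n_repeats, iter.max = 100)$cluster)
  } else {
    labels <- cluster::pam(m, k = n_clusters, cluster.only = TRUE)
  }
  stats::setNames(as.integer(labels), colnames(values))
}

# Evaluate expr under a temporary RNG state seeded with `seed` (NULL = use
# the current stream), restoring the caller's stream afterwards.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Kruskal-Wallis comparison of score groups
#'
#' Rank-based H statistic with tie correction and chi-squared p-value, for
#' comparing e.g. the ARI scores of several selectors. When every value is
#' identical the test is degenerate and H = 0, p = 1 is returned.
#'
#' @param scores list of numeric vectors, one per group (>= 2 non-empty
#'   groups).
#' @return named numeric vector `c(H = ..., p = ...)`.
#' @export
kruskal_wallis <- function(scores) {
  if (!is.list(scores) || length(scores) < 2L || any(lengths(scores) == 0L))
    stop("'scores' must be a list of >= 2 non-empty numeric vectors")
  vals <- unlist(scores, use.names = FALSE)
  if (length(unique(vals)) == 1L) return(c(H = 0, p = 1))
  kt <- stats::kruskal.test(scores)
  c(H = unname(kt$statistic), p = unname(kt$p.value))
}

#' Benchmark feature selectors by subtype-clustering agreement
#'
#' Runs each selector, restricts the matrix to its selected features and the
#' subtype-labelled samples, clusters those samples into as many clusters as
#' there are subtypes, and scores the partition against the labels with the
#' adjusted Rand index — one ARI per (selector, clusterer) pair. Subtypes
#' with three or fewer samples are removed before evaluation. The outlier
#' selection is the union of the up- and down-regulated feature tables; the
#' COPA-rank comparator is sized to match it.
#'
#' @param x a fully observed [expression_matrix()] object.
#' @param subtype_labels named character vector, sample id -> subtype, for
#'   the samples to be clustered (typically the tumour samples).
#' @param methods selectors to run, subset of
#'   `c("mcopa", "copa", "de", "variance")`.
#' @param clusterers subset of `c("kmeans", "pam")`.
#' @param params [outlier_params()] for the outlier run.
#' @param variance_k size of the variance selection (default 1000).
#' @param de_alpha adjusted-p threshold of the DE selector (default 0.01).
#' @param n_repeats k-means restarts (default 20).
#' @param seed integer; per-cell seeds are derived from it.
#' @return numeric matrix of ARI scores (selectors x clusterers), with the
#'   per-method selected feature lists attached as attribute
#'   `"selections"`. A selector that selects no features scores `NA`.
#' @export
evaluate_selection <- function(x, subtype_labels,
                               methods = c("mcopa", "copa", "de", "variance"),
                               clusterers = c("kmeans", "pam"),
                               params = outlier_params(),
                               variance_k = 1000, de_alpha = 0.01,
                               n_repeats = 20, seed = 1) {
  stopifnot(inherits(x, "copa_matrix"))
  methods <- match.arg(methods, several.ok = TRUE)
  clusterers <- match.arg(clusterers, several.ok = TRUE)
  unknown <- setdiff(names(subtype_labels), colnames(x$values))
  if (length(unknown))
    stop("label file references unknown sample(s): ", paste(unknown, collapse = ", "))

  sizes <- table(subtype_labels)
  keep_types <- names(sizes)[sizes > 3L]
  if (length(keep_types) < 2L)
    stop("fewer than two subtypes with more than three samples")
  labels <- subtype_labels[subtype_labels %in% keep_types]
  n_clusters <- length(keep_types)

  selections <- list()
  # the outlier selection must exist before the COPA ranking can be sized to it
  for (m in unique(c(intersect(methods, "mcopa"), methods))) {
    selections[[m]] <- switch(m,
      mcopa = {
        res <- run_mcopa(x, params)
        unique(c(res$up$feature_id, res$down$feature_id))
      },
      copa = {
        k <- if (!is.null(selections$mcopa)) max(length(selections$mcopa), 1L) else variance_k
        copa_rank_select(x, k = k, pct = params$upper_percentile, params = params)$features
      },
      de = de_select(x, alpha = de_alpha)$features,
      variance = variance_select(x, k = variance_k)$features)
  }

  ari <- matrix(NA_real_, length(methods), length(clusterers),
                dimnames = list(methods, clusterers))
  cell <- 0L
  for (m in methods) {
    feats <- selections[[m]]
    for (cl in clusterers) {
      cell <- cell + 1L
      if (length(feats) == 0L) next
      sub <- x$values[feats, names(labels), drop = FALSE]
      part <- cluster_samples(sub, method = cl, n_clusters = n_clusters,
                              n_repeats = n_repeats,
                              seed = if (is.null(seed)) NULL else seed + cell)
      ari[m, cl] <- adjusted_rand_index(part, labels)
    }
  }
  attr(ari, "selections") <- selections
  ari
}
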