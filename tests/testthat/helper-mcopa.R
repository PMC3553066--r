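# Shared fixtures and independent oracles for the test suite.

# Build a copa_matrix from a plain matrix, auto-naming rows/columns.
make_matrix <- function(values, n_normal) {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("f%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  expression_matrix(values, n_normal)
}

# Craft a copa_transform object directly, so fences/calls can be unit-tested
# with exactly known transformed values.
make_transform <- function(values, n_normal) {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("f%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  structure(list(
    values = values,
    stats = data.frame(feature_id = rownames(values),
                       centre = 0, scale = 1,
                       degenerate = apply(values, 1L, function(r) all(r == r[1L])),
                       stringsAsFactors = FALSE),
    scale_mode = "meanad", n_normal = as.integer(n_normal)
  ), class = "copa_transform")
}

# Independently coded textbook quantile estimators (Hyndman & Fan types
# 1, 2 and 4-9), written from the h-index definitions, not from stats::quantile.
oracle_quantile <- function(x, p, type) {
  x <- sort(x)
  n <- length(x)
  if (type == 1) {
    if (p == 0) return(x[1L])
    return(x[ceiling(n * p)])
  }
  if (type == 2) {
    if (p == 0) return(x[1L])
    np <- n * p
    j <- floor(np)
    if (abs(np - j) < 1e-12 && j >= 1L) return((x[j] + x[min(j + 1L, n)]) / 2)
    return(x[ceiling(np)])
  }
  h <- switch(as.character(type),
              "4" = n * p,
              "5" = n * p + 0.5,
              "6" = (n + 1) * p,
              "7" = (n - 1) * p + 1,
              "8" = (n + 1 / 3) * p + 1 / 3,
              "9" = (n + 1 / 4) * p + 3 / 8)
  h <- min(max(h, 1), n)
  fl <- floor(h)
  x[fl] + (h - fl) * (x[min(fl + 1L, n)] - x[fl])
}

# Brute-force adjusted Rand index from the 2x2 pair-agreement table
# (Hubert & Arabie closed form) -- a different route than the contingency
# pair-count formula used by the package.
oracle_ari <- function(k, l) {
  n <- length(k)
  a <- b <- c2 <- d <- 0
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    sk <- k[i] == k[j]
    sl <- l[i] == l[j]
    if (sk && sl) a <- a + 1
    else if (sk && !sl) b <- b + 1
    else if (!sk && sl) c2 <- c2 + 1
    else d <- d + 1
  }
  denom <- (a + b) * (b + d) + (a + c2) * (c2 + d)
  if (denom == 0) return(if (b + c2 == 0) 1 else 0)
  2 * (a * d - b * c2) / denom
}

# All permutations of a vector (for exhaustive small-n enumerations).
all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    out <- c(out, lapply(all_perms(v[-i]), function(p) c(v[i], p)))
  out
}

# Total within-cluster sum of squares of a labelled sample partition
# (samples = columns of `values`).
wss_of <- function(values, labels) {
  m <- t(values)
  sum(vapply(unique(labels), function(cl) {
    rows <- m[labels == cl, , drop = FALSE]
    sum(sweep(rows, 2L, colMeans(rows))^2)
  }, numeric(1L)))
}

# Deterministic smooth background row used by the filter-criteria fixtures:
# regular enough that no background value crosses a Tukey fence.
toy_background <- function() seq(0.1, 0.8, by = 0.1)
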