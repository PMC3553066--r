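#' Construct an expression matrix with a normal/tumour split
#'
#' The basic data container of the package: a numeric feature-by-sample
#' matrix of normalised (log2-scale) expression values in which the first
#' `n_normal` columns are the normal (control) samples and the remaining
#' columns are the tumour (case) samples. When an experiment has no true
#' normal samples the first `n_normal` columns are simply treated as the
#' control set.
#'
#' @param values numeric matrix, rows = features, columns = samples. Row and
#'   column names are required and must be unique; they become the feature
#'   and sample identifiers.
#' @param n_normal number of leading columns that are normal/control samples
#'   (at least 1, and strictly less than the number of columns).
#' @return An object of class `copa_matrix`: a list with elements `values`
#'   (the matrix) and `n_normal`.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("f", 1:3), paste0("s", 1:4)))
#' x <- expression_matrix(m, n_normal = 2)
#' tumour_samples(x)
#' @export
expression_matrix <- function(values, n_normal) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have feature (row) and sample (column) names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature identifiers")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers")
  n_normal <- as.integer(n_normal)
  if (length(n_normal) != 1L || is.na(n_normal) || n_normal < 1L)
    stop("'n_normal' must be a single integer >= 1")
  if (n_normal >= ncol(values))
    stop("no tumour samples: 'n_normal' must be smaller than the number of samples")
  structure(list(values = values, n_normal = n_normal), class = "copa_matrix")
}

#' @export
print.copa_matrix <- function(x, ...) {
  cat(sprintf("copa_matrix: %d features x %d samples (%d normal, %d tumour)\n",
              nrow(x$values), ncol(x$values), x$n_normal,
              ncol(x$values) - x$n_normal))
  invisible(x)
}

#' @export
dim.copa_matrix <- function(x) dim(x$values)

#' Accessors for a `copa_matrix`
#'
#' @param x a [expression_matrix()] object.
#' @return `features()` and `samples()` return identifier vectors;
#'   `normal_samples()` / `tumour_samples()` return the sample identifiers of
#'   each group.
#' @export
features <- function(x) rownames(x$values)

#' @rdname features
#' @export
samples <- function(x) colnames(x$values)

#' @rdname features
#' @export
normal_samples <- function(x) colnames(x$values)[seq_len(x$n_normal)]

#' @rdname features
#' @export
tumour_samples <- function(x) colnames(x$values)[-seq_len(x$n_normal)]

#' Read an expression matrix from tab-separated text
#'
#' Expects a header row of sample identifiers, a first column of feature
#' identifiers, and tab-separated numeric values; missing values may be
#' encoded as an empty field or `NA`. Normal samples must occupy the first
#' `n_normal` columns.
#'
#' @param path path to the TSV file.
#' @param n_normal number of leading normal/control columns.
#' @return A [expression_matrix()] object.
#' @export
read_matrix <- function(path, n_normal) {
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "", blank.lines.skip = TRUE)
  if (length(unique(nf)) > 1L)
    stop("ragged rows: lines have differing field counts (",
         paste(unique(nf), collapse = ", "), ")")
  d <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                         na.strings = c("", "NA"), quote = "",
                         stringsAsFactors = FALSE)
  if (ncol(d) < 2L) stop("matrix file must have a feature-id column and at least one sample")
  ids <- as.character(d[[1L]])
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate feature identifiers: ", paste(utils::head(dup, 5), collapse = ", "))
  }
  vals <- as.matrix(d[, -1L, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric values in matrix body")
  rownames(vals) <- ids
  expression_matrix(vals, n_normal)
}

#' Write an expression matrix as tab-separated text
#'
#' Inverse of [read_matrix()]: a header row of sample identifiers, feature
#' identifiers in the first column, `NA` for missing values.
#'
#' @param x a `copa_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path) {
  d <- data.frame(feature_id = rownames(x$values), x$values,
                  check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column probe-to-gene annotation table
#'
#' @param path TSV with columns probe id, gene symbol (header optional is not
#'   supported: a header line is expected).
#' @return named character vector mapping probe id to gene symbol.
#' @export
read_annotation <- function(path) {
  d <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                         stringsAsFactors = FALSE, quote = "")
  if (ncol(d) < 2L) stop("annotation file must have two columns (probe, gene)")
  probes <- as.character(d[[1L]])
  if (anyDuplicated(probes)) stop("duplicate probe identifiers in annotation")
  stats::setNames(as.character(d[[2L]]), probes)
}

#' Read a two-column sample-to-subtype label table
#'
#' @param path TSV with header and columns sample id, subtype label.
#' @return named character vector mapping sample id to subtype.
#' @export
read_subtype_labels <- function(path) {
  d <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                         stringsAsFactors = FALSE, quote = "")
  if (ncol(d) < 2L) stop("label file must have two columns (sample, subtype)")
  ids <- as.character(d[[1L]])
  if (anyDuplicated(ids)) stop("duplicate sample identifiers in label file")
  stats::setNames(as.character(d[[2L]]), ids)
}

#' Map probe identifiers to gene symbols
#'
#' Many-to-one mappings are allowed (several probes may map to one gene);
#' the gene list is de-duplicated and probes absent from the annotation are
#' reported separately rather than silently dropped.
#'
#' @param probes character vector of probe/feature identifiers.
#' @param annotation named character vector as returned by
#'   [read_annotation()].
#' @return list with elements `genes` (unique mapped symbols, in first-probe
#'   order), `unmapped` (probes with no annotation entry) and `map`
#'   (data frame of the successful probe-to-gene pairs).
#' @export
probes_to_genes <- function(probes, annotation) {
  probes <- as.character(probes)
  hit <- probes %in% names(annotation)
  map <- data.frame(probe_id = probes[hit],
                    gene = unname(annotation[probes[hit]]),
                    stringsAsFactors = FALSE)
  list(genes = unique(map$gene), unmapped = probes[!hit], map = map)
}
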