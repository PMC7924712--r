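#' Expression matrix with sample and feature identifiers
#'
#' Light container for a real-valued samples-by-features matrix. Rows are
#' samples (arrays, cells, ...), columns are features (genes, probes, ...).
#' All entries must be finite; identifier vectors must match the matrix
#' dimensions and contain no duplicates.
#'
#' @param values Numeric matrix, `m` samples by `n` features.
#' @param feature_ids Character vector of `n` unique feature identifiers.
#'   Defaults to the column names of `values`, or `"f1".."fn"`.
#' @param sample_ids Character vector of `m` unique sample identifiers.
#'   Defaults to the row names of `values`, or `"s1".."sm"`.
#' @return An object of class `feature_matrix` with elements `values`,
#'   `feature_ids`, `sample_ids`.
#' @examples
#' fm <- feature_matrix(matrix(rnorm(12), 3, 4))
#' dim(fm$values)
#' @export
feature_matrix <- function(values, feature_ids = NULL, sample_ids = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("`values` must have at least one row and one column", call. = FALSE)
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite entry at sample row %d, feature column %d",
                 bad[1L], bad[2L]), call. = FALSE)
  }
  if (is.null(feature_ids)) {
    feature_ids <- colnames(values)
    if (is.null(feature_ids)) feature_ids <- paste0("f", seq_len(ncol(values)))
  }
  if (is.null(sample_ids)) {
    sample_ids <- rownames(values)
    if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(values)))
  }
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (length(feature_ids) != ncol(values))
    stop("length(feature_ids) must equal ncol(values)", call. = FALSE)
  if (length(sample_ids) != nrow(values))
    stop("length(sample_ids) must equal nrow(values)", call. = FALSE)
  if (anyDuplicated(feature_ids))
    stop("duplicate feature identifiers: ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifiers: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  dimnames(values) <- list(sample_ids, feature_ids)
  structure(list(values = values,
                 feature_ids = feature_ids,
                 sample_ids = sample_ids),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d samples x %d features\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Number of samples / features of a feature matrix
#' @param x A `feature_matrix`.
#' @return Integer count.
#' @export
n_samples <- function(x) nrow(x$values)

#' @rdname n_samples
#' @export
n_features <- function(x) ncol(x$values)

#' Subset a feature matrix by samples and/or features
#'
#' @param x A `feature_matrix`.
#' @param samples Integer/logical index over samples, or `NULL` for all.
#' @param features Integer/logical index over features, or `NULL` for all.
#' @return A new `feature_matrix`.
#' @export
subset_matrix <- function(x, samples = NULL, features = NULL) {
  stopifnot(inherits(x, "feature_matrix"))
  if (is.null(samples)) samples <- seq_len(nrow(x$values))
  if (is.null(features)) features <- seq_len(ncol(x$values))
  feature_matrix(x$values[samples, features, drop = FALSE],
                 feature_ids = x$feature_ids[features],
                 sample_ids = x$sample_ids[samples])
}

#' Labeled dataset: expression matrix plus class labels
#'
#' Couples a [feature_matrix()] with a categorical label per sample. The
#' class order is fixed once, lexicographically over label strings, and is
#' used by every per-class structure downstream (class subsets, per-class
#' feature sets, ensemble members, vote vectors).
#'
#' @param matrix A `feature_matrix`.
#' @param labels Vector of length `n_samples(matrix)`; coerced to character.
#' @return Object of class `labeled_dataset` with elements `matrix`,
#'   `labels` (character) and `classes` (sorted unique labels).
#' @export
labeled_dataset <- function(matrix, labels) {
  stopifnot(inherits(matrix, "feature_matrix"))
  labels <- as.character(labels)
  if (length(labels) != n_samples(matrix))
    stop("labels length must equal the number of samples", call. = FALSE)
  if (anyNA(labels)) stop("labels must not contain NA", call. = FALSE)
  classes <- sort(unique(labels))
  if (length(classes) < 1L) stop("at least one class required", call. = FALSE)
  structure(list(matrix = matrix, labels = labels, classes = classes),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("labeled_dataset: %d samples x %d features, %d classes (%s)\n",
              n_samples(x$matrix), n_features(x$matrix), length(x$classes),
              paste(x$classes, collapse = ", ")))
  invisible(x)
}
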