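#' Table dialect for delimited expression matrices
#'
#' The orientation is always explicit: readers never guess silently.
#'
#' @param delimiter Field separator, `"\t"` (default) or `","`.
#' @param orientation `"samples_by_features"` (default) or
#'   `"features_by_samples"`; the reader always returns samples as rows.
#' @param header Logical, first line holds column identifiers (default
#'   `TRUE`).
#' @param row_ids Logical, first field of each row is an identifier
#'   (default `TRUE`).
#' @return Object of class `table_dialect`.
#' @export
table_dialect <- function(delimiter = "\t",
                          orientation = c("samples_by_features",
                                          "features_by_samples"),
                          header = TRUE, row_ids = TRUE) {
  orientation <- match.arg(orientation)
  if (!delimiter %in% c("\t", ","))
    stop("`delimiter` must be tab or comma", call. = FALSE)
  structure(list(delimiter = delimiter, orientation = orientation,
                 header = isTRUE(header), row_ids = isTRUE(row_ids)),
            class = "table_dialect")
}

#' Read a delimited expression table
#'
#' Parses under the given dialect and returns a validated
#' [feature_matrix()] in samples-as-rows orientation regardless of the
#' on-disk orientation. Missing or non-numeric cells and duplicate
#' identifiers are errors naming the offending coordinates.
#'
#' @param path File path.
#' @param dialect A [table_dialect()].
#' @return A [feature_matrix()].
#' @export
read_expression_table <- function(path, dialect = table_dialect()) {
  stopifnot(inherits(dialect, "table_dialect"))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, sep = dialect$delimiter,
                           header = dialect$header,
                           row.names = if (dialect$row_ids) 1L else NULL,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  M <- as.matrix(raw)
  num <- suppressWarnings(matrix(as.numeric(M), nrow(M), ncol(M)))
  bad <- which(is.na(num) | M == "", arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-numeric or missing cell at row '%s', column '%s'",
                 if (dialect$row_ids) rownames(M)[bad[1, 1]] else bad[1, 1],
                 if (dialect$header) colnames(M)[bad[1, 2]] else bad[1, 2]),
         call. = FALSE)
  dimnames(num) <- dimnames(M)
  if (dialect$orientation == "features_by_samples") num <- t(num)
  feature_matrix(num)
}

#' Write a feature matrix as a delimited table
#'
#' @param fm A [feature_matrix()].
#' @param path Output path.
#' @param dialect A [table_dialect()] (values transposed on disk when
#'   orientation is `"features_by_samples"`).
#' @export
write_expression_table <- function(fm, path, dialect = table_dialect()) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(dialect, "table_dialect"))
  V <- fm$values
  if (dialect$orientation == "features_by_samples") V <- t(V)
  utils::write.table(format(V, digits = 17, trim = TRUE, scientific = NA),
                     path, sep = dialect$delimiter, quote = FALSE,
                     col.names = NA, row.names = TRUE)
  invisible(path)
}

#' Read / write a two-column sample label file
#'
#' Tab-separated with header `sample_id<TAB>label`.
#'
#' @param path File path.
#' @return Named character vector of labels (names = sample ids).
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) stop("label file needs two columns", call. = FALSE)
  stats::setNames(df[[2L]], df[[1L]])
}

#' @rdname read_labels
#' @param labels Named character vector (names = sample ids).
#' @export
write_labels <- function(labels, path) {
  utils::write.table(data.frame(sample_id = names(labels),
                                label = unname(labels)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a feature ranking (or per-class feature sets) as TSV
#'
#' Columns: `class` (only for per-class sets), `rank` (starting at 1),
#' `feature_id`, `score` (full precision). Per-class sets are grouped by
#' class in class order.
#'
#' @param x A `feature_ranking` or `class_feature_sets` object.
#' @param path Output path.
#' @export
write_ranking <- function(x, path) {
  fmt <- function(v) formatC(v, digits = 17, format = "g")
  if (inherits(x, "feature_ranking")) {
    df <- data.frame(rank = seq_along(x$order), feature_id = x$feature_ids,
                     score = fmt(x$scores))
  } else if (inherits(x, "class_feature_sets")) {
    df <- do.call(rbind, lapply(x$classes, function(cl) {
      r <- x$rankings[[cl]]
      data.frame(class = cl, rank = seq_along(r$order),
                 feature_id = r$feature_ids, score = fmt(r$scores))
    }))
  } else stop("unsupported ranking object", call. = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a ranking TSV written by [write_ranking()]
#'
#' @param path File path.
#' @return A data.frame with columns (`class`,) `rank`, `feature_id`,
#'   `score`.
#' @export
read_ranking <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$score <- as.numeric(df$score)
  df
}

#' Read a datasets-by-methods score table for rank testing
#'
#' Tab-separated, header of method names, first column dataset ids.
#'
#' @param path File path.
#' @return Numeric matrix with dimnames.
#' @export
read_rank_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, row.names = 1L, check.names = FALSE)
  M <- as.matrix(df)
  if (!is.numeric(M) || anyNA(M))
    stop("rank table must be fully numeric", call. = FALSE)
  M
}

#' Serialize an `acm_report`
#'
#' Writes the report as JSON (summary, records, config echo) and, when
#' `tsv_path` is given, the per-fold records as a tidy TSV with columns
#' `fold`, `j`, `metric`, `value`.
#'
#' @param report An `acm_report`.
#' @param json_path JSON output path.
#' @param tsv_path Optional tidy TSV output path.
#' @export
write_acm_report <- function(report, json_path, tsv_path = NULL) {
  stopifnot(inherits(report, "acm_report"))
  cfg <- report$config
  payload <- list(
    mode = report$mode,
    config = list(m = cfg$m, K = cfg$K, seed = cfg$seed,
                  classifier = cfg$classifier$name,
                  classifier_params = cfg$classifier$params,
                  faithful = cfg$faithful, stratified = cfg$stratified,
                  smote_k = cfg$smote_k,
                  feature_grid = cfg$feature_grid,
                  smba = cfg$smba[c("lam", "alpha", "rho", "delta", "eta",
                                    "q", "max_iter")]),
    summary = report$summary,
    records = report$records)
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  if (!is.null(tsv_path)) {
    rec <- report$records
    long <- do.call(rbind, lapply(
      c("accuracy", "precision", "recall", "f1", "auc"),
      function(mt) data.frame(fold = rec$fold, j = rec$j, metric = mt,
                              value = rec[[mt]])))
    utils::write.table(long, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(json_path)
}
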