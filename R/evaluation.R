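#' Z-score standardization fit on training data
#'
#' Per-feature centring and scaling with TRAIN statistics only; the same
#' transform is applied to the other matrices (e.g. a test fold). The
#' population standard deviation (divisor m) is used; zero-variance
#' features have their sd clamped to 1, so they map to all zeros.
#'
#' @param train A [feature_matrix()].
#' @param others List of [feature_matrix()] objects sharing the feature
#'   space (may be empty).
#' @return List with `train`, `others` (standardized), `center`, `scale`.
#' @export
zscore_fit_apply <- function(train, others = list()) {
  stopifnot(inherits(train, "feature_matrix"))
  V <- train$values
  ctr <- colMeans(V)
  sd_pop <- sqrt(colMeans(sweep(V, 2L, ctr)^2))
  scl <- ifelse(sd_pop > 0, sd_pop, 1)
  tr <- sweep(sweep(V, 2L, ctr), 2L, scl, "/")
  std <- function(fm) {
    stopifnot(inherits(fm, "feature_matrix"))
    feature_matrix(sweep(sweep(fm$values, 2L, ctr), 2L, scl, "/"),
                   feature_ids = fm$feature_ids, sample_ids = fm$sample_ids)
  }
  list(train = feature_matrix(tr, feature_ids = train$feature_ids,
                              sample_ids = train$sample_ids),
       others = lapply(others, std),
       center = ctr, scale = scl)
}

#' Deterministic K-fold split, optionally stratified
#'
#' Indices are shuffled under `seed` and dealt cyclically into folds;
#' stratification deals each class separately with a running fold counter,
#' so overall fold sizes differ by at most 1 and class proportions are
#' preserved within one sample.
#'
#' @param labels Label vector (only its length is used when
#'   `stratified = FALSE`).
#' @param K Number of folds (`2 <= K <= length(labels)`).
#' @param seed RNG seed.
#' @param stratified Preserve class proportions per fold (default `TRUE`).
#' @return List of `K` lists with integer elements `train` and `test`.
#' @export
kfold_split <- function(labels, K, seed = 1L, stratified = TRUE) {
  n <- length(labels)
  K <- as.integer(K)
  if (K < 2L || K > n) stop("`K` must lie in [2, n]", call. = FALSE)
  labels <- as.character(labels)
  assign_fold <- integer(n)
  withr::with_seed(seed, {
    counter <- 0L
    groups <- if (stratified) sort(unique(labels)) else "all"
    for (g in groups) {
      idx <- if (stratified) which(labels == g) else seq_len(n)
      idx <- idx[sample.int(length(idx))]
      assign_fold[idx] <- ((counter + seq_along(idx) - 1L) %% K) + 1L
      counter <- counter + length(idx)
    }
  })
  lapply(seq_len(K), function(k)
    list(train = which(assign_fold != k), test = which(assign_fold == k)))
}

## Rank-based (Mann-Whitney) AUC of scores for a binary indicator
binary_auc <- function(score, positive) {
  n_pos <- sum(positive); n_neg <- sum(!positive)
  r <- rank(score)
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Classification metrics for one evaluation
#'
#' Accuracy plus macro-averaged precision, recall and F1 over the classes
#' present in `y_true` (per-class zero denominators contribute 0), and
#' macro one-vs-rest AUC over the columns of `score_matrix` (classes with
#' no positive or no negative sample in `y_true` are skipped).
#'
#' @param y_true,y_pred Character vectors of equal length.
#' @param score_matrix Numeric matrix, samples by classes, columns named or
#'   ordered by `classes`; `NULL` to skip AUC (reported as `NA`).
#' @param classes Ordered full class set.
#' @return List of class `metric_record`: `accuracy`, `precision`,
#'   `recall`, `f1`, `auc`.
#' @export
compute_metrics <- function(y_true, y_pred, score_matrix = NULL,
                            classes = sort(unique(y_true))) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length", call. = FALSE)
  present <- classes[classes %in% y_true]
  acc <- mean(y_true == y_pred)
  prf <- vapply(present, function(cl) {
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    c(p, r, f)
  }, numeric(3))
  auc <- NA_real_
  if (!is.null(score_matrix)) {
    if (length(present) < 2L)
      stop("AUC undefined: y_true contains a single class", call. = FALSE)
    aucs <- vapply(present, function(cl) {
      ci <- match(cl, classes)
      binary_auc(score_matrix[, ci], y_true == cl)
    }, numeric(1))
    auc <- mean(aucs)
  }
  structure(list(accuracy = acc,
                 precision = mean(prf[1, ]),
                 recall = mean(prf[2, ]),
                 f1 = mean(prf[3, ]),
                 auc = auc),
            class = "metric_record")
}

## shared config validation
check_config <- function(dataset, config) {
  stopifnot(inherits(dataset, "labeled_dataset"),
            inherits(config, "csfs_config"))
  if (config$m > n_features(dataset$matrix))
    stop("`m` exceeds the number of features", call. = FALSE)
  counts <- table(dataset$labels)
  if (config$stratified && config$K > min(counts))
    stop("stratified K-fold requires K <= smallest class size", call. = FALSE)
}

#' Configuration for the cross-validated evaluation loop
#'
#' @param m Maximum features per class (default 80).
#' @param K Fold count (default 5).
#' @param classifier A [classifier_spec()] (default linear SVM, C = 1).
#' @param smba An [smba_params()] object.
#' @param seed Master seed; all fold/SMOTE/tie-break seeds derive from it.
#' @param faithful If `TRUE`, standardize, SMOTE-balance and shuffle the
#'   FULL dataset before fold splitting (the printed algorithm order, which
#'   leaks test information into preprocessing); default `FALSE` fits the
#'   z-score and SMOTE inside each training fold only.
#' @param feature_grid Feature counts `j` to evaluate (default `1:m`).
#' @param stratified Stratified folds (default `TRUE`).
#' @param smote_k SMOTE neighbourhood size (default 5).
#' @return Object of class `csfs_config`.
#' @export
csfs_config <- function(m = 80L, K = 5L,
                        classifier = classifier_spec("linear_svm"),
                        smba = smba_params(), seed = 1L, faithful = FALSE,
                        feature_grid = NULL, stratified = TRUE,
                        smote_k = 5L) {
  m <- as.integer(m); K <- as.integer(K)
  if (m < 1L) stop("`m` must be >= 1", call. = FALSE)
  if (is.null(feature_grid)) feature_grid <- seq_len(m)
  feature_grid <- as.integer(feature_grid)
  if (any(feature_grid < 1L) || any(feature_grid > m))
    stop("`feature_grid` must lie within [1, m]", call. = FALSE)
  stopifnot(inherits(classifier, "classifier_spec"),
            inherits(smba, "smba_params"))
  structure(list(m = m, K = K, classifier = classifier, smba = smba,
                 seed = as.integer(seed), faithful = isTRUE(faithful),
                 feature_grid = feature_grid, stratified = isTRUE(stratified),
                 smote_k = as.integer(smote_k)),
            class = "csfs_config")
}

## assemble per-fold records into the report
make_acm_report <- function(records, config, mode) {
  df <- do.call(rbind, records)
  rownames(df) <- NULL
  agg <- do.call(rbind, lapply(split(df, df$j), function(d) {
    data.frame(j = d$j[1],
               accuracy_mean = mean(d$accuracy), accuracy_sd = stats::sd(d$accuracy),
               precision_mean = mean(d$precision), precision_sd = stats::sd(d$precision),
               recall_mean = mean(d$recall), recall_sd = stats::sd(d$recall),
               f1_mean = mean(d$f1), f1_sd = stats::sd(d$f1),
               auc_mean = mean(d$auc), auc_sd = stats::sd(d$auc))
  }))
  agg <- agg[order(agg$j), , drop = FALSE]
  rownames(agg) <- NULL
  structure(list(records = df, summary = agg, config = config, mode = mode),
            class = "acm_report")
}

#' @export
print.acm_report <- function(x, ...) {
  cat(sprintf("acm_report (%s): %d folds x %d feature counts\n",
              x$mode, x$config$K, length(x$config$feature_grid)))
  print(utils::head(x$summary))
  invisible(x)
}

record_row <- function(fold, j, m) {
  data.frame(fold = fold, j = j, accuracy = m$accuracy,
             precision = m$precision, recall = m$recall, f1 = m$f1,
             auc = m$auc)
}

## faithful-mode preprocessing: z-score, SMOTE and shuffle the whole
## dataset before splitting, as printed in the original algorithm
preprocess_faithful <- function(dataset, config) {
  z <- zscore_fit_apply(dataset$matrix)
  ds <- labeled_dataset(z$train, dataset$labels)
  ds <- smote_balance(ds, config$smote_k, seed = config$seed + 7L)
  perm <- withr::with_seed(config$seed + 11L,
                           sample.int(n_samples(ds$matrix)))
  labeled_dataset(subset_matrix(ds$matrix, samples = perm), ds$labels[perm])
}

#' Cross-validated evaluation of class-specific selection (Algorithm loop)
#'
#' For each fold: standardize (train statistics), SMOTE-balance the
#' training fold, run the per-class sparse selector once, then for every
#' `j` in `feature_grid` build the per-class ensemble on the top-`j`
#' features, predict the test fold and record metrics. In `faithful` mode
#' the whole dataset is standardized, balanced and shuffled before fold
#' splitting instead (reproducing the printed ordering; a leakage warning
#' is logged). The per-class solve is done once per fold and reused across
#' all `j` (rankings are prefix-consistent).
#'
#' @param dataset A [labeled_dataset()] with at least 2 classes.
#' @param config A [csfs_config()].
#' @return An `acm_report`: per-fold `records` (fold, j, metrics) and
#'   per-j `summary` (mean and sd across folds).
#' @export
run_csfs_cv <- function(dataset, config = csfs_config()) {
  check_config(dataset, config)
  if (length(dataset$classes) < 2L)
    stop("at least 2 classes required", call. = FALSE)
  faithful <- config$faithful
  if (faithful) {
    message("faithful mode: z-score/SMOTE/shuffle applied to the FULL ",
            "dataset BEFORE fold splitting (information leakage)")
    dataset <- preprocess_faithful(dataset, config)
  }
  folds <- kfold_split(dataset$labels, config$K, seed = config$seed,
                       stratified = config$stratified)
  records <- list()
  for (k in seq_along(folds)) {
    tr_idx <- folds[[k]]$train; te_idx <- folds[[k]]$test
    tr_fm <- subset_matrix(dataset$matrix, samples = tr_idx)
    te_fm <- subset_matrix(dataset$matrix, samples = te_idx)
    tr_lab <- dataset$labels[tr_idx]; te_lab <- dataset$labels[te_idx]
    if (!faithful) {
      z <- zscore_fit_apply(tr_fm, list(te_fm))
      tr_fm <- z$train; te_fm <- z$others[[1]]
    }
    train <- labeled_dataset(tr_fm, tr_lab)
    if (!faithful)
      train <- smote_balance(train, config$smote_k,
                             seed = config$seed + 100L * k)
    fsets <- tryCatch(
      select_class_specific(train, config$smba, config$m),
      error = function(e) stop(sprintf("fold %d: %s", k,
                                       conditionMessage(e)), call. = FALSE))
    for (j in config$feature_grid) {
      ens <- build_ensemble(train, fsets, j, config$classifier,
                            seed = config$seed + 100L * k + j)
      pred <- predict(ens, te_fm)
      met <- compute_metrics(te_lab, pred$labels, pred$scores,
                             classes = dataset$classes)
      records[[length(records) + 1L]] <- record_row(k, j, met)
    }
  }
  make_acm_report(records, config, mode = "csfs")
}

#' Cross-validated evaluation of whole-dataset (class-agnostic) selection
#'
#' Same protocol as [run_csfs_cv()] but the sparse selector is run once on
#' the whole training fold (no class separation) and a single classifier is
#' trained on the top-`j` features — the traditional all-classes selector
#' against which the class-specific variant is compared.
#'
#' @inheritParams run_csfs_cv
#' @return An `acm_report`.
#' @export
run_smba_cv <- function(dataset, config = csfs_config()) {
  check_config(dataset, config)
  if (length(dataset$classes) < 2L)
    stop("at least 2 classes required", call. = FALSE)
  faithful <- config$faithful
  if (faithful) {
    message("faithful mode: z-score/SMOTE/shuffle applied to the FULL ",
            "dataset BEFORE fold splitting (information leakage)")
    dataset <- preprocess_faithful(dataset, config)
  }
  folds <- kfold_split(dataset$labels, config$K, seed = config$seed,
                       stratified = config$stratified)
  records <- list()
  for (k in seq_along(folds)) {
    tr_idx <- folds[[k]]$train; te_idx <- folds[[k]]$test
    tr_fm <- subset_matrix(dataset$matrix, samples = tr_idx)
    te_fm <- subset_matrix(dataset$matrix, samples = te_idx)
    tr_lab <- dataset$labels[tr_idx]; te_lab <- dataset$labels[te_idx]
    if (!faithful) {
      z <- zscore_fit_apply(tr_fm, list(te_fm))
      tr_fm <- z$train; te_fm <- z$others[[1]]
    }
    train <- labeled_dataset(tr_fm, tr_lab)
    if (!faithful)
      train <- smote_balance(train, config$smote_k,
                             seed = config$seed + 100L * k)
    ranking <- rank_features(solve_smba(train$matrix, config$smba))
    for (j in config$feature_grid) {
      feats <- ranking$order[seq_len(j)]
      model <- train_classifier(config$classifier,
                                train$matrix$values[, feats, drop = FALSE],
                                train$labels, classes = dataset$classes)
      pr <- predict_classifier(model, te_fm$values[, feats, drop = FALSE])
      met <- compute_metrics(te_lab, pr$labels, pr$scores,
                             classes = dataset$classes)
      records[[length(records) + 1L]] <- record_row(k, j, met)
    }
  }
  make_acm_report(records, config, mode = "smba")
}
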