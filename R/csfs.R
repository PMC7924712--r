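#' Split a labelled dataset into one subset per class
#'
#' @param dataset A [labeled_dataset()].
#' @return List (in class order) of objects with elements `class_label` and
#'   `matrix` (a [feature_matrix()] holding that class's samples, original
#'   order preserved).
#' @export
separate_by_class <- function(dataset) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  lapply(dataset$classes, function(cl) {
    idx <- which(dataset$labels == cl)
    structure(list(class_label = cl,
                   matrix = subset_matrix(dataset$matrix, samples = idx)),
              class = "class_subset")
  })
}

#' Balance class sizes by SMOTE
#'
#' Every minority class is grown to the majority class size by synthesising
#' points `x + u (x' - x)` with `u ~ Uniform(0, 1)`, where `x` is a randomly
#' chosen real sample of the class and `x'` one of its `k_neighbors` nearest
#' same-class neighbours (Euclidean distance). Original samples are kept
#' verbatim; synthetic samples are appended with identifiers
#' `"syn_<class>_<t>"`. `k_neighbors` is capped at (class size - 1).
#'
#' @param dataset A [labeled_dataset()].
#' @param k_neighbors Neighbourhood size (default 5).
#' @param seed RNG seed; the operation is deterministic given it.
#' @return A balanced [labeled_dataset()]. Returned unchanged when the
#'   classes are already balanced.
#' @export
smote_balance <- function(dataset, k_neighbors = 5L, seed = 1L) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  if (!is.numeric(k_neighbors) || k_neighbors < 1L)
    stop("`k_neighbors` must be >= 1", call. = FALSE)
  counts <- table(factor(dataset$labels, levels = dataset$classes))
  maj <- max(counts)
  if (all(counts == maj)) return(dataset)
  V <- dataset$matrix$values
  new_rows <- list(); new_ids <- character(0); new_labels <- character(0)
  withr::with_seed(seed, {
    for (cl in dataset$classes) {
      idx <- which(dataset$labels == cl)
      need <- maj - length(idx)
      if (need == 0L) next
      if (length(idx) < 2L)
        stop(sprintf(
          "class '%s' has a single sample; SMOTE cannot synthesize", cl),
          call. = FALSE)
      k <- min(k_neighbors, length(idx) - 1L)
      Xc <- V[idx, , drop = FALSE]
      D2 <- as.matrix(stats::dist(Xc))^2
      diag(D2) <- Inf
      nn <- t(apply(D2, 1L, function(r) order(r)[seq_len(k)]))
      for (t in seq_len(need)) {
        base <- sample.int(length(idx), 1L)
        nb <- nn[base, sample.int(k, 1L)]
        u <- stats::runif(1)
        new_rows[[length(new_rows) + 1L]] <-
          Xc[base, ] + u * (Xc[nb, ] - Xc[base, ])
        new_ids <- c(new_ids, sprintf("syn_%s_%d", cl, t))
        new_labels <- c(new_labels, cl)
      }
    }
  })
  Vall <- rbind(V, do.call(rbind, new_rows))
  fm <- feature_matrix(Vall,
                       feature_ids = dataset$matrix$feature_ids,
                       sample_ids = c(dataset$matrix$sample_ids, new_ids))
  labeled_dataset(fm, c(dataset$labels, new_labels))
}

#' Per-class feature selection by intra-class sparse self-representation
#'
#' For each class (in class order), [solve_smba()] is run on that class's
#' sample submatrix over all features, and the top `m` of the resulting
#' [rank_features()] ordering are stored. All rankings live in the global
#' feature index space and may overlap across classes.
#'
#' @param train A [labeled_dataset()].
#' @param params An [smba_params()].
#' @param m Features to keep per class (`<= n_features`).
#' @return Object of class `class_feature_sets`: list `rankings` (one
#'   truncated `feature_ranking` per class, class order), `classes`, `m`.
#' @export
select_class_specific <- function(train, params = smba_params(), m) {
  stopifnot(inherits(train, "labeled_dataset"))
  n <- n_features(train$matrix)
  m <- as.integer(m)
  if (m < 1L || m > n) stop("`m` must lie in [1, n_features]", call. = FALSE)
  rankings <- lapply(separate_by_class(train), function(sub) {
    r <- tryCatch(rank_features(solve_smba(sub$matrix, params)),
                  error = function(e) stop(sprintf(
                    "class '%s': %s", sub$class_label, conditionMessage(e)),
                    call. = FALSE))
    r$order <- r$order[seq_len(m)]
    r$scores <- r$scores[seq_len(m)]
    r$feature_ids <- r$feature_ids[seq_len(m)]
    r
  })
  names(rankings) <- train$classes
  structure(list(rankings = rankings, classes = train$classes, m = m),
            class = "class_feature_sets")
}

#' Build the per-class ensemble classifier
#'
#' Member i is trained on ALL training samples (every class) restricted to
#' the top-`j` features selected for class i. Members are stored in class
#' order; the ensemble carries a seed used only for random tie-breaking at
#' prediction time.
#'
#' @param train A [labeled_dataset()] (typically standardized and balanced).
#' @param fsets A `class_feature_sets` from [select_class_specific()].
#' @param j Features per member (`<=` each ranking's length).
#' @param spec A [classifier_spec()].
#' @param seed Tie-break RNG seed.
#' @return Object of class `csfs_ensemble`.
#' @export
build_ensemble <- function(train, fsets, j, spec = classifier_spec(),
                           seed = 1L) {
  stopifnot(inherits(train, "labeled_dataset"),
            inherits(fsets, "class_feature_sets"),
            inherits(spec, "classifier_spec"))
  if (length(train$classes) < 2L)
    stop("at least 2 classes required for an ensemble", call. = FALSE)
  if (!identical(train$classes, fsets$classes))
    stop("class sets of `train` and `fsets` differ", call. = FALSE)
  j <- as.integer(j)
  if (j < 1L || any(vapply(fsets$rankings, function(r) length(r$order),
                           integer(1)) < j))
    stop("`j` exceeds the length of a class ranking", call. = FALSE)
  members <- lapply(seq_along(train$classes), function(i) {
    feats <- fsets$rankings[[i]]$order[seq_len(j)]
    model <- tryCatch(
      train_classifier(spec, train$matrix$values[, feats, drop = FALSE],
                       train$labels, classes = train$classes),
      error = function(e) stop(sprintf(
        "member '%s': %s", train$classes[i], conditionMessage(e)),
        call. = FALSE))
    list(class_label = train$classes[i], features = feats, model = model)
  })
  structure(list(members = members, classes = train$classes,
                 classifier_spec = spec, j = j, seed = seed,
                 n_features = n_features(train$matrix),
                 feature_ids = train$matrix$feature_ids),
            class = "csfs_ensemble")
}

#' Cascaded self-vote / majority decision rule
#'
#' Member i of the ensemble is associated with class `classes[i]`; a
#' "self-vote" is member i predicting its own class. The cascade is:
#' (a) exactly one self-vote: that class wins (`self_vote_unique`);
#' (a-tie) several self-votes: total votes over ALL members are counted and
#' the self-voted class with the most votes wins (`self_vote_majority`),
#' residual ties drawn uniformly (`random_tie`);
#' (b) no self-vote: the class with the most total votes wins
#' (`plain_majority`), ties drawn uniformly (`random_tie`).
#'
#' @param predictions Character vector of length `c`; element i is member
#'   i's predicted class.
#' @param classes Ordered class vector of length `c >= 2`.
#' @param rng Optional function(n) returning an index in `1..n`; defaults
#'   to `sample.int` (uses the current RNG stream).
#' @return Object of class `prediction_outcome`: `label`, `rule_path`
#'   (one of `self_vote_unique`, `self_vote_majority`, `plain_majority`,
#'   `random_tie`), `votes` (named per-class counts, summing to `c`).
#' @export
decide_majority <- function(predictions, classes, rng = NULL) {
  predictions <- as.character(predictions)
  if (length(predictions) != length(classes))
    stop("one prediction per ensemble member required", call. = FALSE)
  if (!all(predictions %in% classes))
    stop("prediction outside the class set", call. = FALSE)
  if (is.null(rng)) rng <- function(n) sample.int(n, 1L)
  votes <- table(factor(predictions, levels = classes))
  S <- which(predictions == classes)
  pick <- function(cands) {
    if (length(cands) == 1L) return(list(label = cands, tie = FALSE))
    list(label = cands[rng(length(cands))], tie = TRUE)
  }
  if (length(S) == 1L) {
    label <- classes[S]; path <- "self_vote_unique"
  } else if (length(S) > 1L) {
    cand <- classes[S]
    winners <- cand[votes[cand] == max(votes[cand])]
    res <- pick(winners)
    label <- res$label
    path <- if (res$tie) "random_tie" else "self_vote_majority"
  } else {
    winners <- classes[votes == max(votes)]
    res <- pick(winners)
    label <- res$label
    path <- if (res$tie) "random_tie" else "plain_majority"
  }
  structure(list(label = label, rule_path = path,
                 votes = stats::setNames(as.integer(votes), classes)),
            class = "prediction_outcome")
}

#' Predict with a class-specific ensemble
#'
#' Each member predicts every sample on its own feature subset; the
#' per-sample label is produced by [decide_majority()]. Tie-breaks consume
#' a stream seeded with the ensemble's seed, in sample order, so repeated
#' calls are reproducible.
#'
#' @param object A `csfs_ensemble`.
#' @param samples A [feature_matrix()] over the training feature space.
#' @param ... Unused.
#' @return Object of class `csfs_predictions`: `outcomes` (list of
#'   `prediction_outcome`), `labels` (character vector), `scores`
#'   (vote-share matrix, samples by classes; used as ROC scores).
#' @export
predict.csfs_ensemble <- function(object, samples, ...) {
  stopifnot(inherits(samples, "feature_matrix"))
  if (n_features(samples) != object$n_features ||
      !identical(samples$feature_ids, object$feature_ids))
    stop("sample feature space does not match the ensemble's training space",
         call. = FALSE)
  V <- samples$values
  c_n <- length(object$classes)
  member_preds <- vapply(object$members, function(mb) {
    predict_classifier(mb$model, V[, mb$features, drop = FALSE])$labels
  }, character(nrow(V)))
  member_preds <- matrix(member_preds, nrow = nrow(V), ncol = c_n)
  outcomes <- vector("list", nrow(V))
  withr::with_seed(object$seed, {
    for (i in seq_len(nrow(V)))
      outcomes[[i]] <- decide_majority(member_preds[i, ], object$classes)
  })
  labels <- vapply(outcomes, `[[`, character(1), "label")
  scores <- t(vapply(outcomes, function(o) o$votes / c_n, numeric(c_n)))
  colnames(scores) <- object$classes
  structure(list(outcomes = outcomes, labels = labels, scores = scores),
            class = "csfs_predictions")
}
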