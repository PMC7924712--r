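#' Classifier specification
#'
#' Opaque description of the base classifier used by the ensemble and the
#' cross-validation loops. Three deterministic classifiers are built in:
#'
#' * `"linear_svm"` — one-vs-rest linear support vector machine with
#'   squared hinge loss, objective `0.5 ||w||^2 + C sum_i xi_i^2`, solved
#'   by BFGS from a zero start (default `C = 1`).
#' * `"knn"` — k-nearest neighbours with Euclidean distance (default
#'   `k = 5`); vote ties broken by smaller mean neighbour distance, then
#'   class order.
#' * `"naive_bayes"` — Gaussian naive Bayes with per-class feature means
#'   and variances (variance floor 1e-9) and empirical class priors.
#'
#' @param name One of `"linear_svm"`, `"knn"`, `"naive_bayes"`.
#' @param ... Hyperparameters (`C` for the SVM, `k` for KNN).
#' @return Object of class `classifier_spec`.
#' @export
classifier_spec <- function(name = c("linear_svm", "knn", "naive_bayes"),
                            ...) {
  name <- match.arg(name)
  pars <- list(...)
  defaults <- switch(name,
    linear_svm = list(C = 1),
    knn = list(k = 5L),
    naive_bayes = list())
  for (nm in names(pars)) defaults[[nm]] <- pars[[nm]]
  structure(list(name = name, params = defaults), class = "classifier_spec")
}

#' Train a classifier on a labelled matrix
#'
#' @param spec A [classifier_spec()].
#' @param x Numeric matrix, samples by features.
#' @param y Character vector of labels.
#' @param classes Full ordered class set the model must predict over
#'   (defaults to `sort(unique(y))`).
#' @return Object of class `trained_classifier`.
#' @export
train_classifier <- function(spec, x, y, classes = NULL) {
  stopifnot(inherits(spec, "classifier_spec"), is.matrix(x))
  y <- as.character(y)
  if (length(y) != nrow(x)) stop("labels/rows mismatch", call. = FALSE)
  if (is.null(classes)) classes <- sort(unique(y))
  fit <- switch(spec$name,
    linear_svm = fit_linear_svm(x, y, classes, spec$params$C),
    knn = list(x = x, y = y, k = spec$params$k),
    naive_bayes = fit_naive_bayes(x, y, classes))
  structure(list(spec = spec, classes = classes, fit = fit,
                 n_features = ncol(x)),
            class = "trained_classifier")
}

fit_linear_svm <- function(x, y, classes, C) {
  p <- ncol(x)
  W <- matrix(0, p, length(classes))
  b <- numeric(length(classes))
  for (ci in seq_along(classes)) {
    yy <- ifelse(y == classes[ci], 1, -1)
    if (all(yy == 1) || all(yy == -1)) {
      # class absent (or alone): constant margin in its favour/disfavour
      b[ci] <- if (all(yy == 1)) 1 else -1
      next
    }
    obj <- function(par) {
      w <- par[seq_len(p)]; b0 <- par[p + 1L]
      marg <- pmax(0, 1 - yy * (drop(x %*% w) + b0))
      0.5 * sum(w * w) + C * sum(marg * marg)
    }
    grad <- function(par) {
      w <- par[seq_len(p)]; b0 <- par[p + 1L]
      marg <- pmax(0, 1 - yy * (drop(x %*% w) + b0))
      coef <- -2 * C * yy * marg
      c(w + drop(crossprod(x, coef)), sum(coef))
    }
    opt <- stats::optim(rep(0, p + 1L), obj, grad, method = "BFGS",
                        control = list(maxit = 200, reltol = 1e-10))
    W[, ci] <- opt$par[seq_len(p)]
    b[ci] <- opt$par[p + 1L]
  }
  list(W = W, b = b)
}

fit_naive_bayes <- function(x, y, classes) {
  mu <- s2 <- matrix(NA_real_, length(classes), ncol(x))
  prior <- numeric(length(classes))
  for (ci in seq_along(classes)) {
    idx <- which(y == classes[ci])
    prior[ci] <- length(idx) / length(y)
    if (length(idx) == 0L) { mu[ci, ] <- 0; s2[ci, ] <- 1; next }
    xi <- x[idx, , drop = FALSE]
    mu[ci, ] <- colMeans(xi)
    s2[ci, ] <- pmax(colMeans(xi^2) - mu[ci, ]^2, 1e-9)
  }
  list(mu = mu, s2 = s2, prior = pmax(prior, 1e-12))
}

#' Predict labels and per-class scores
#'
#' @param model A `trained_classifier`.
#' @param x Numeric matrix with the same number of columns the model was
#'   trained on.
#' @return List with `labels` (character vector) and `scores` (numeric
#'   matrix, samples by classes; larger = more confident).
#' @export
predict_classifier <- function(model, x) {
  stopifnot(inherits(model, "trained_classifier"), is.matrix(x))
  if (ncol(x) != model$n_features)
    stop(sprintf("model expects %d features, got %d",
                 model$n_features, ncol(x)), call. = FALSE)
  classes <- model$classes
  scores <- switch(model$spec$name,
    linear_svm = sweep(x %*% model$fit$W, 2L, model$fit$b, "+"),
    knn = knn_scores(model$fit, x, classes),
    naive_bayes = nb_scores(model$fit, x, classes))
  colnames(scores) <- classes
  labels <- classes[max.col(scores, ties.method = "first")]
  list(labels = labels, scores = scores)
}

knn_scores <- function(fit, x, classes) {
  k <- min(fit$k, nrow(fit$x))
  tr <- fit$x
  trn2 <- rowSums(tr * tr)
  out <- matrix(0, nrow(x), length(classes))
  for (i in seq_len(nrow(x))) {
    d2 <- trn2 - 2 * drop(tr %*% x[i, ]) + sum(x[i, ]^2)
    nn <- order(d2)[seq_len(k)]                 # stable: distance then index
    votes <- table(factor(fit$y[nn], levels = classes))
    sc <- as.numeric(votes) / k
    # break vote ties deterministically by smaller mean neighbour distance
    top <- which(sc == max(sc))
    if (length(top) > 1L) {
      md <- vapply(top, function(ci) {
        sel <- nn[fit$y[nn] == classes[ci]]
        mean(d2[sel])
      }, numeric(1))
      sc[top[which.min(md)]] <- sc[top[which.min(md)]] + 1e-9
    }
    out[i, ] <- sc
  }
  out
}

nb_scores <- function(fit, x, classes) {
  out <- matrix(0, nrow(x), length(classes))
  for (ci in seq_along(classes)) {
    ll <- -0.5 * sweep(sweep(x, 2L, fit$mu[ci, ])^2, 2L, fit$s2[ci, ], "/")
    out[, ci] <- rowSums(sweep(ll, 2L, 0.5 * log(2 * pi * fit$s2[ci, ]))) +
      log(fit$prior[ci])
  }
  out
}
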