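#' Parameters for the sparse self-representation solver
#'
#' The solver minimises `0.5 * ||X - X C||_F^2 + lambda * ||C||_{1,q}`
#' subject to the affine constraint `1' C = 1'` (every column of `C` sums
#' to one). `||C||_{1,q}` is the sum of the q-norms of the rows of `C`;
#' driving rows to zero deselects the corresponding features.
#'
#' Exactly one of `lam` / `alpha` may be supplied. With `alpha`, the
#' regularization weight is tied to the data scale as
#' `lambda = lambda_reference(X) / alpha`, so `alpha` is a dimensionless
#' sparsity dial (larger `alpha` = weaker penalty = denser solution).
#'
#' @param lam Regularization weight `lambda > 0`, or `NULL` to use `alpha`.
#' @param alpha Dimensionless divisor `> 1`; ignored when `lam` is given.
#'   Default 2 when neither is supplied.
#' @param rho ADMM penalty parameter `> 0`, or `NULL` (default) to set
#'   `rho = lambda` at solve time. The penalty only affects the iteration
#'   path, not the optimum; matching it to the scale of the regularizer
#'   keeps iteration counts low across data scales. Kept constant within a
#'   run so the factorization of the constrained least-squares system is
#'   reused across iterations.
#' @param delta Convergence tolerance on the relative primal residual
#'   `||beta - theta||_F / max(1, ||beta||_F)` (default 1e-5).
#' @param eta Representative threshold in `[0, 1)`: features whose relative
#'   row norm exceeds `eta` are reported by [find_representatives()].
#' @param q Row-norm order, 2 (default) or `Inf`.
#' @param max_iter Iteration cap (default 5000).
#' @param seed Optional RNG seed carried in the parameter object for
#'   bookkeeping; the solver itself is deterministic.
#' @return Object of class `smba_params`.
#' @export
smba_params <- function(lam = NULL, alpha = NULL, rho = NULL, delta = 1e-5,
                        eta = 1e-4, q = 2, max_iter = 5000L, seed = NULL) {
  if (!is.null(lam) && !is.null(alpha))
    stop("supply exactly one of `lam` and `alpha`", call. = FALSE)
  if (is.null(lam) && is.null(alpha)) alpha <- 2
  if (!is.null(lam) && (!is.numeric(lam) || lam <= 0))
    stop("`lam` must be a positive number", call. = FALSE)
  if (!is.null(alpha) && (!is.numeric(alpha) || alpha <= 1))
    stop("`alpha` must be > 1", call. = FALSE)
  if (!is.null(rho) && (!is.numeric(rho) || rho <= 0))
    stop("`rho` must be > 0", call. = FALSE)
  if (!is.numeric(delta) || delta <= 0) stop("`delta` must be > 0", call. = FALSE)
  if (!is.numeric(eta) || eta < 0 || eta >= 1)
    stop("`eta` must lie in [0, 1)", call. = FALSE)
  if (!(identical(as.numeric(q), 2) || identical(as.numeric(q), Inf)))
    stop("`q` must be 2 or Inf", call. = FALSE)
  max_iter <- as.integer(max_iter)
  if (max_iter < 1L) stop("`max_iter` must be >= 1", call. = FALSE)
  structure(list(lam = lam, alpha = alpha, rho = rho, delta = delta,
                 eta = eta, q = as.numeric(q), max_iter = max_iter,
                 seed = seed),
            class = "smba_params")
}

## q-norms of the rows of a matrix
row_qnorms <- function(M, q = 2) {
  if (identical(as.numeric(q), 2)) sqrt(rowSums(M * M))
  else apply(abs(M), 1L, max)
}

dual_qnorm <- function(v, q = 2) {
  if (identical(as.numeric(q), 2)) sqrt(sum(v * v)) else sum(abs(v))
}

#' Data-dependent regularization scale
#'
#' Returns `max_i || G e_i - mean_col(G) ||_qbar`, where `G = X'X` is the
#' feature Gram matrix, `mean_col(G)` the mean of its columns, and `qbar`
#' the dual of `q` (2 for q = 2, 1 for q = Inf). The value is positive for
#' any non-constant `X` and scales quadratically with the data
#' (`lambda_reference(c X) = c^2 lambda_reference(X)`), making
#' `lambda = lambda_reference(X) / alpha` a scale-free parameterization.
#'
#' @param X A [feature_matrix()] with at least 2 features.
#' @param q Row-norm order (2 or `Inf`).
#' @return Positive scalar.
#' @export
lambda_reference <- function(X, q = 2) {
  stopifnot(inherits(X, "feature_matrix"))
  V <- X$values
  if (ncol(V) < 2L) stop("at least 2 features required", call. = FALSE)
  G <- crossprod(V)
  mu <- rowMeans(G)
  D <- G - mu   # subtract the column-mean vector from every column
  vals <- if (identical(as.numeric(q), 2)) sqrt(colSums(D * D))
          else colSums(abs(D))
  out <- max(vals)
  if (out <= .Machine$double.eps * max(1, max(abs(G))))
    stop("degenerate data: all features identical up to the Gram column mean",
         call. = FALSE)
  out
}

#' Objective of the affine self-representation problem
#'
#' Evaluates `0.5 * ||X - X C||_F^2 + lam * sum_i ||c^i||_q` where `c^i` is
#' the i-th row of `C`.
#'
#' @param X A [feature_matrix()].
#' @param C Square numeric matrix with side `n_features(X)`.
#' @param lam Nonnegative regularization weight.
#' @param q Row-norm order (2 or `Inf`).
#' @return Nonnegative scalar.
#' @export
compute_objective <- function(X, C, lam, q = 2) {
  stopifnot(inherits(X, "feature_matrix"))
  if (!is.matrix(C) || nrow(C) != ncol(C))
    stop("`C` must be a square matrix", call. = FALSE)
  if (nrow(C) != n_features(X))
    stop(sprintf("dimension mismatch: C is %dx%d but X has %d features",
                 nrow(C), ncol(C), n_features(X)), call. = FALSE)
  if (!all(is.finite(C))) stop("`C` contains non-finite entries", call. = FALSE)
  if (!is.numeric(lam) || lam < 0) stop("`lam` must be >= 0", call. = FALSE)
  V <- X$values
  R <- V - V %*% C
  0.5 * sum(R * R) + lam * sum(row_qnorms(C, q))
}

## Euclidean projection onto the l1 ball of radius z (Duchi et al. 2008)
proj_l1_ball <- function(v, z = 1) {
  a <- abs(v)
  if (sum(a) <= z) return(v)
  u <- sort(a, decreasing = TRUE)
  cs <- cumsum(u)
  k <- max(which(u - (cs - z) / seq_along(u) > 0))
  tau <- (cs[k] - z) / k
  sign(v) * pmax(a - tau, 0)
}

#' Row-wise proximal operator of the l1,q penalty
#'
#' For `q = 2` each row is shrunk toward zero by `kappa` in Euclidean norm:
#' `row <- max(0, 1 - kappa / ||row||_2) * row` (a zero row stays zero).
#' For `q = Inf` the prox is computed through Moreau decomposition with the
#' projection onto the l1 ball of radius `kappa`.
#'
#' @param M Numeric matrix.
#' @param kappa Nonnegative threshold.
#' @param q Row-norm order (2 or `Inf`).
#' @return Matrix of the same shape.
#' @export
block_soft_threshold <- function(M, kappa, q = 2) {
  if (!is.numeric(kappa) || length(kappa) != 1L || kappa < 0)
    stop("`kappa` must be a single nonnegative number", call. = FALSE)
  if (!is.matrix(M)) stop("`M` must be a matrix", call. = FALSE)
  if (kappa == 0) return(M)
  if (identical(as.numeric(q), 2)) {
    rn <- sqrt(rowSums(M * M))
    scale <- ifelse(rn > 0, pmax(0, 1 - kappa / rn), 0)
    M * scale
  } else {
    t(apply(M, 1L, function(r) r - proj_l1_ball(r, kappa)))
  }
}

#' Solve the affine-constrained ridge subproblem of the ADMM iteration
#'
#' Returns the unique minimizer of
#' `0.5 ||X - X beta||_F^2 + (rho/2) ||beta - theta + mu/rho||_F^2`
#' subject to `1' beta = 1'`, given the Gram matrix `gram = X'X` and the
#' stationarity right-hand side `target = gram + rho*theta - mu`. Each
#' column solves an equality-constrained quadratic program through its
#' KKT system; the `(n+1) x (n+1)` KKT matrix is shared by all columns.
#'
#' @param gram Symmetric positive semidefinite `n x n` matrix `X'X`.
#' @param target `n x n` right-hand side `gram + rho*theta - mu`.
#' @param rho Positive ADMM penalty.
#' @return `n x n` matrix whose columns each sum to 1.
#' @export
solve_beta_subproblem <- function(gram, target, rho) {
  if (!is.matrix(gram) || nrow(gram) != ncol(gram))
    stop("`gram` must be square", call. = FALSE)
  if (!is.matrix(target) || !all(dim(target) == dim(gram)))
    stop("`target` must match `gram` in shape", call. = FALSE)
  if (!is.numeric(rho) || rho <= 0) stop("`rho` must be > 0", call. = FALSE)
  n <- nrow(gram)
  ones <- rep(1, n)
  K <- rbind(cbind(gram + rho * diag(n), ones), c(ones, 0))
  rhs <- rbind(target, rep(1, n))
  sol <- solve(K, rhs)
  sol[seq_len(n), , drop = FALSE]
}

## Closure applying the constrained ridge solve with precomputed factors.
## When m < n the inverse of (G + rho I) is applied through the Woodbury
## identity using a Cholesky factor of (rho I_m + V V'), which keeps the
## per-iteration cost at O(m n^2) instead of O(n^3).
make_beta_solver <- function(V, rho) {
  n <- ncol(V)
  m <- nrow(V)
  ones <- rep(1, n)
  if (m < n) {
    S <- diag(rho, m) + tcrossprod(V)
    R <- chol(S)
    Ainv <- function(Y) {
      (Y - crossprod(V, backsolve(R, forwardsolve(t(R), V %*% Y)))) / rho
    }
    a <- Ainv(matrix(ones, ncol = 1))  # (G + rho I)^{-1} 1
    s <- sum(a)
    function(target) {
      U <- Ainv(target)
      U - a %*% matrix((colSums(U) - 1) / s, nrow = 1)
    }
  } else {
    A <- crossprod(V) + diag(rho, n)
    R <- chol(A)
    Ainv <- function(Y) backsolve(R, forwardsolve(t(R), Y))
    a <- Ainv(matrix(ones, ncol = 1))
    s <- sum(a)
    function(target) {
      U <- Ainv(target)
      U - a %*% matrix((colSums(U) - 1) / s, nrow = 1)
    }
  }
}

## reference R implementation of the ADMM loop; the hot q = 2 path runs
## the identical sequence in compiled code (.admm_l12_cpp)
admm_loop_r <- function(V, lam, rho, delta, max_iter, q) {
  n <- ncol(V)
  G <- crossprod(V)
  beta_solve <- make_beta_solver(V, rho)
  theta <- matrix(0, n, n)
  mu <- matrix(0, n, n)
  eps <- Inf
  t <- 0L
  residuals <- numeric(0)
  while (eps > delta && t < max_iter) {
    beta <- beta_solve(G + rho * theta - mu)
    theta <- block_soft_threshold(beta + mu / rho, lam / rho, q)
    mu <- mu + rho * (beta - theta)
    d <- beta - theta
    eps <- sqrt(sum(d * d)) / max(1, sqrt(sum(beta * beta)))
    t <- t + 1L
    residuals[t] <- eps
  }
  list(theta = theta, iterations = t, eps = eps, residuals = residuals)
}

#' Solve the sparse self-representation problem by ADMM
#'
#' Minimises `0.5 ||X - X C||_F^2 + lambda ||C||_{1,q}` subject to
#' `1'C = 1'` by alternating (i) the affine-constrained ridge update of
#' `beta`, (ii) the row-wise soft-threshold update of `theta` with
#' threshold `lambda/rho`, and (iii) the dual update
#' `mu <- mu + rho (beta - theta)`. Iteration stops when the relative
#' primal residual drops to `delta` or `max_iter` is reached. The solver is
#' deterministic; it performs no standardization (callers standardize).
#'
#' @param X A [feature_matrix()].
#' @param params An [smba_params()] object.
#' @return Object of class `coefficient_matrix` with elements `C` (the
#'   theta iterate, exactly row-sparse), `row_norms`, `objective`,
#'   `constraint_residual` (max deviation of column sums of `C` from 1),
#'   `converged`, `iterations`, `residuals` (primal residual trace),
#'   `lam`, `q`, `feature_ids`.
#' @export
solve_smba <- function(X, params = smba_params()) {
  stopifnot(inherits(X, "feature_matrix"), inherits(params, "smba_params"))
  V <- X$values
  n <- ncol(V)
  if (all(V == 0)) stop("all-zero data matrix", call. = FALSE)
  q <- params$q
  if (n == 1L) {
    C <- matrix(1, 1, 1)
    lam <- if (!is.null(params$lam)) params$lam else 1
    return(structure(list(C = C, row_norms = 1,
                          objective = compute_objective(X, C, lam, q),
                          constraint_residual = 0, converged = TRUE,
                          iterations = 1L, residuals = 0, lam = lam, q = q,
                          feature_ids = X$feature_ids),
                     class = "coefficient_matrix"))
  }
  lam <- if (!is.null(params$lam)) params$lam
         else lambda_reference(X, q) / params$alpha
  rho <- if (!is.null(params$rho)) params$rho else lam
  if (identical(as.numeric(q), 2)) {
    # hot path: compiled loop, identical update sequence
    res <- .admm_l12_cpp(V, lam, rho, params$delta, params$max_iter)
    theta <- res$theta
    t <- res$iterations
    eps <- res$eps
    residuals <- res$residuals
  } else {
    res <- admm_loop_r(V, lam, rho, params$delta, params$max_iter, q)
    theta <- res$theta
    t <- res$iterations
    eps <- res$eps
    residuals <- res$residuals
  }
  converged <- eps <= params$delta
  if (!converged)
    warning(sprintf(
      "ADMM did not converge in %d iterations (residual %.3g > delta %.3g)",
      t, eps, params$delta), call. = FALSE)
  C <- theta
  structure(list(C = C,
                 row_norms = row_qnorms(C, q),
                 objective = compute_objective(X, C, lam, q),
                 constraint_residual = max(abs(colSums(C) - 1)),
                 converged = converged,
                 iterations = t,
                 residuals = residuals,
                 lam = lam, q = q,
                 feature_ids = X$feature_ids),
            class = "coefficient_matrix")
}

#' @export
print.coefficient_matrix <- function(x, ...) {
  cat(sprintf(paste0("coefficient_matrix: %d features, objective %.6g, ",
                     "%d nonzero rows, %s in %d iterations\n"),
              length(x$row_norms), x$objective,
              sum(x$row_norms > 0),
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  invisible(x)
}

#' Rank features by the row norms of the coefficient matrix
#'
#' A feature whose coefficient row has a large q-norm takes a large part in
#' reconstructing the other features and is ranked first. Ties are broken
#' by ascending original feature index (stable).
#'
#' @param C A `coefficient_matrix` from [solve_smba()].
#' @param q Row-norm order; defaults to the order stored in `C`.
#' @return Object of class `feature_ranking` with `order` (feature indices,
#'   best first), `scores` (row norms in ranked order, non-increasing) and
#'   `feature_ids` (identifiers in ranked order).
#' @export
rank_features <- function(C, q = NULL) {
  stopifnot(inherits(C, "coefficient_matrix"))
  if (is.null(q)) q <- C$q
  rn <- row_qnorms(C$C, q)
  ord <- order(-rn)   # base order() is stable: ties keep ascending index
  structure(list(order = ord, scores = rn[ord],
                 feature_ids = C$feature_ids[ord]),
            class = "feature_ranking")
}

#' @export
print.feature_ranking <- function(x, ...) {
  k <- min(10L, length(x$order))
  cat(sprintf("feature_ranking: %d features; top %d: %s\n",
              length(x$order), k,
              paste(x$feature_ids[seq_len(k)], collapse = ", ")))
  invisible(x)
}

#' Representative features above a relative row-norm threshold
#'
#' Returns the indices of features whose row norm exceeds `eta` times the
#' maximum row norm, ordered as in [rank_features()].
#'
#' @param C A `coefficient_matrix`.
#' @param eta Threshold in `[0, 1)`.
#' @param q Row-norm order; defaults to the order stored in `C`.
#' @return Integer vector of feature indices (best first).
#' @export
find_representatives <- function(C, eta = 1e-4, q = NULL) {
  stopifnot(inherits(C, "coefficient_matrix"))
  if (!is.numeric(eta) || eta < 0 || eta >= 1)
    stop("`eta` must lie in [0, 1)", call. = FALSE)
  if (is.null(q)) q <- C$q
  rn <- row_qnorms(C$C, q)
  mx <- max(rn)
  if (mx == 0)
    stop("all coefficient rows are zero; lambda is too large", call. = FALSE)
  ranking <- rank_features(C, q)
  keep <- rn[ranking$order] / mx > eta
  ranking$order[keep]
}
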