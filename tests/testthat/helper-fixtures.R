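# shared fixtures and independent oracles for the test suite

random_fm <- function(m, n, seed = 1) {
  withr::with_seed(seed, feature_matrix(matrix(rnorm(m * n), m, n)))
}

random_labeled <- function(m_per_class, classes = 2, n = 10, seed = 1) {
  withr::with_seed(seed, {
    m <- m_per_class * classes
    fm <- feature_matrix(matrix(rnorm(m * n), m, n))
    labeled_dataset(fm, rep(letters[seq_len(classes)], each = m_per_class))
  })
}

# brute-force objective recomputation, term by term, independent of
# compute_objective's vectorized path
oracle_objective <- function(V, C, lam, q = 2) {
  resid <- 0
  for (j in seq_len(ncol(V))) {
    r <- V[, j] - V %*% C[, j]
    resid <- resid + sum(r^2)
  }
  pen <- 0
  for (i in seq_len(nrow(C))) {
    pen <- pen + if (identical(as.numeric(q), 2)) sqrt(sum(C[i, ]^2))
                 else max(abs(C[i, ]))
  }
  0.5 * resid + lam * pen
}

# independent equality-constrained ridge solver: eliminate the affine
# constraint with a null-space parameterization and solve the reduced
# unconstrained least-squares problem column by column
oracle_beta <- function(V, theta, mu, rho) {
  n <- ncol(V)
  ones <- rep(1, n)
  Z <- qr.Q(qr(cbind(ones, diag(n))))[, 2:n, drop = FALSE]  # null space of 1'
  part <- ones / n                                          # particular solution
  out <- matrix(0, n, n)
  A <- rbind(V, sqrt(rho) * diag(n))
  for (j in seq_len(n)) {
    v <- theta[, j] - mu[, j] / rho
    b <- c(V[, j], sqrt(rho) * v)
    # beta_j = part + Z t ; minimize ||A (part + Z t) - b||^2
    t_hat <- qr.solve(A %*% Z, b - A %*% part)
    out[, j] <- part + Z %*% t_hat
  }
  out
}

# exhaustive re-implementation of the cascaded decision rule, written
# directly from the rule statement (independent of decide_majority)
oracle_decide <- function(predictions, classes) {
  votes <- vapply(classes, function(cl) sum(predictions == cl), numeric(1))
  S <- which(predictions == classes)
  if (length(S) == 1L) return(list(winners = classes[S], path = "self_vote_unique"))
  if (length(S) > 1L) {
    cand <- classes[S]
    winners <- cand[votes[cand] == max(votes[cand])]
    return(list(winners = winners,
                path = if (length(winners) == 1L) "self_vote_majority"
                       else "random_tie"))
  }
  winners <- classes[votes == max(votes)]
  list(winners = winners,
       path = if (length(winners) == 1L) "plain_majority" else "random_tie")
}

# run the shipped scipy SLSQP oracle on a list of problems
run_convex_oracle <- function(problems) {
  script <- system.file("oracle", "smba_oracle.py", package = "smbacsfs")
  stopifnot(nzchar(script))
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  jsonlite::write_json(problems, fin, digits = NA, auto_unbox = TRUE)
  status <- system2("python", c(script, fin, fout))
  stopifnot(status == 0L)
  unlist(jsonlite::read_json(fout))
}
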