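#' Specification for self-expressive synthetic data
#'
#' Describes a matrix whose dependent feature columns are affine
#' combinations of a small set of representative columns — the structure
#' the self-representation model with the `1'C = 1'` constraint assumes.
#'
#' @param m Samples (rows); default 30.
#' @param n_rep True representative features; default 5.
#' @param n_dep Dependent features; default 35.
#' @param noise_sd Gaussian noise sd added to dependent columns; default 0.
#' @param weight_concentration Dirichlet concentration of the affine
#'   weights (default 1, i.e. uniform on the simplex).
#' @param signed If `TRUE`, weights are signed but still sum to 1
#'   (harder instances); default `FALSE` keeps convex weights.
#' @param seed RNG seed.
#' @return Object of class `self_expressive_spec`.
#' @export
self_expressive_spec <- function(m = 30L, n_rep = 5L, n_dep = 35L,
                                 noise_sd = 0, weight_concentration = 1,
                                 signed = FALSE, seed = 1L) {
  stopifnot(m >= 1L, n_rep >= 1L, n_dep >= 0L, noise_sd >= 0,
            weight_concentration > 0)
  structure(list(m = as.integer(m), n_rep = as.integer(n_rep),
                 n_dep = as.integer(n_dep), noise_sd = noise_sd,
                 weight_concentration = weight_concentration,
                 signed = isTRUE(signed), seed = as.integer(seed)),
            class = "self_expressive_spec")
}

#' Generate a self-expressive matrix with known representatives
#'
#' Representative columns are iid standard normal; each dependent column is
#' `sum_r w_r rep_r + noise`, with weights drawn from a Dirichlet
#' distribution (so they sum to 1, matching the affine constraint). Columns
#' are randomly permuted so representative positions are not trivially
#' first. Pure function of the spec (seed included).
#'
#' @param spec A [self_expressive_spec()].
#' @return List with `matrix` (a [feature_matrix()]), `rep_indices` (sorted
#'   column positions of the true representatives), `rep_positions` (same,
#'   aligned with the rows of `weights`), `dep_indices`, and `weights`
#'   (`n_rep` by `n_dep` matrix of affine weights, columns aligned with
#'   `dep_indices`).
#' @export
generate_self_expressive <- function(spec) {
  stopifnot(inherits(spec, "self_expressive_spec"))
  withr::with_seed(spec$seed, {
    R <- matrix(stats::rnorm(spec$m * spec$n_rep), spec$m, spec$n_rep)
    W <- matrix(0, spec$n_rep, spec$n_dep)
    if (spec$n_dep > 0) {
      for (d in seq_len(spec$n_dep)) {
        if (spec$signed) {
          w <- stats::rnorm(spec$n_rep)
          w <- w / sum(w)
          # redraw until the sum is comfortably away from zero
          while (!is.finite(sum(abs(w))) || sum(abs(w)) > 50) {
            w <- stats::rnorm(spec$n_rep); w <- w / sum(w)
          }
        } else {
          g <- stats::rgamma(spec$n_rep, shape = spec$weight_concentration)
          w <- g / sum(g)
        }
        W[, d] <- w
      }
    }
    D <- R %*% W
    if (spec$noise_sd > 0)
      D <- D + matrix(stats::rnorm(spec$m * spec$n_dep, sd = spec$noise_sd),
                      spec$m, spec$n_dep)
    n <- spec$n_rep + spec$n_dep
    perm <- sample.int(n)
    V <- cbind(R, D)[, order(perm), drop = FALSE]
  })
  # original column i lands at position perm[i]; representatives (original
  # 1..n_rep) therefore sit at positions perm[1..n_rep]
  rep_pos <- perm[seq_len(spec$n_rep)]
  dep_idx <- perm[spec$n_rep + seq_len(spec$n_dep)]
  fm <- feature_matrix(V)
  list(matrix = fm, rep_indices = sort(rep_pos), rep_positions = rep_pos,
       dep_indices = dep_idx, weights = W)
}

#' Specification for multi-class data with class-specific feature blocks
#'
#' Emulates the features >> samples, many-classes regime of expression
#' datasets: background features are iid Gaussian noise, and each class
#' has a disjoint block of informative features whose mean is shifted in
#' that class's samples only.
#'
#' @param classes Number of classes `c >= 2`; default 6.
#' @param samples_per_class Scalar or length-`c` vector; default 20.
#' @param n_features Total features; default 500.
#' @param informative_per_class Block size per class; default 20
#'   (`c * informative_per_class <= n_features`).
#' @param effect_size Mean shift of informative features, in units of the
#'   noise sd; default 2.
#' @param noise_sd Background sd; default 1.
#' @param seed RNG seed.
#' @return Object of class `multiclass_spec`.
#' @export
multiclass_spec <- function(classes = 6L, samples_per_class = 20L,
                            n_features = 500L, informative_per_class = 20L,
                            effect_size = 2, noise_sd = 1, seed = 1L) {
  classes <- as.integer(classes)
  stopifnot(classes >= 2L, n_features >= 1L, informative_per_class >= 1L,
            noise_sd > 0, effect_size >= 0)
  if (length(samples_per_class) == 1L)
    samples_per_class <- rep(as.integer(samples_per_class), classes)
  samples_per_class <- as.integer(samples_per_class)
  stopifnot(length(samples_per_class) == classes, all(samples_per_class >= 1L))
  if (classes * informative_per_class > n_features)
    stop("classes * informative_per_class must be <= n_features",
         call. = FALSE)
  structure(list(classes = classes, samples_per_class = samples_per_class,
                 n_features = as.integer(n_features),
                 informative_per_class = as.integer(informative_per_class),
                 effect_size = effect_size, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "multiclass_spec")
}

#' Generate multi-class data with known informative features
#'
#' @param spec A [multiclass_spec()].
#' @return List with `dataset` (a [labeled_dataset()]) and
#'   `informative` (list per class, in class order, of the informative
#'   feature indices).
#' @export
generate_multiclass <- function(spec) {
  stopifnot(inherits(spec, "multiclass_spec"))
  m <- sum(spec$samples_per_class)
  n <- spec$n_features
  ipc <- spec$informative_per_class
  class_names <- sprintf("class%02d", seq_len(spec$classes))
  labels <- rep(class_names, spec$samples_per_class)
  blocks <- lapply(seq_len(spec$classes),
                   function(i) ((i - 1L) * ipc + 1L):(i * ipc))
  withr::with_seed(spec$seed, {
    V <- matrix(stats::rnorm(m * n, sd = spec$noise_sd), m, n)
  })
  shift <- spec$effect_size * spec$noise_sd
  for (i in seq_len(spec$classes)) {
    rows <- which(labels == class_names[i])
    V[rows, blocks[[i]]] <- V[rows, blocks[[i]]] + shift
  }
  fm <- feature_matrix(V, feature_ids = paste0("g", seq_len(n)),
                       sample_ids = paste0("s", seq_len(m)))
  names(blocks) <- class_names
  list(dataset = labeled_dataset(fm, labels), informative = blocks)
}
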