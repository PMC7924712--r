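#' Friedman rank test over a datasets-by-methods score table
#'
#' Scores are ranked within each dataset (row), rank 1 = best, midranks
#' for ties. With `N` datasets and `k` methods of average ranks `R_j`, the
#' statistic is `chi2_F = 12 N / (k (k+1)) * (sum_j R_j^2 - k (k+1)^2 / 4)`
#' with a chi-squared reference distribution on `k - 1` degrees of freedom.
#' The statistic depends on the scores only through within-row ranks, so it
#' is invariant to any within-row monotone transform.
#'
#' @param table Numeric matrix, `N >= 2` datasets (rows) by `k >= 2`
#'   methods (columns); no missing entries.
#' @param higher_is_better If `TRUE` (default) larger scores rank better.
#' @return List with `statistic`, `p_value`, `average_ranks` (named by
#'   method when the table has column names), `N`, `k`.
#' @export
friedman_statistic <- function(table, higher_is_better = TRUE) {
  if (!is.matrix(table)) table <- as.matrix(table)
  if (!is.numeric(table) || anyNA(table))
    stop("`table` must be a numeric matrix without missing entries",
         call. = FALSE)
  N <- nrow(table); k <- ncol(table)
  if (N < 2L || k < 2L)
    stop("at least 2 datasets and 2 methods required", call. = FALSE)
  sgn <- if (higher_is_better) -1 else 1
  ranks <- t(apply(table, 1L, function(r) rank(sgn * r, ties.method = "average")))
  R <- colMeans(ranks)
  stat <- 12 * N / (k * (k + 1)) * (sum(R^2) - k * (k + 1)^2 / 4)
  stat <- max(stat, 0)  # guard tiny negative rounding in the full-tie case
  p <- stats::pchisq(stat, df = k - 1L, lower.tail = FALSE)
  names(R) <- colnames(table)
  list(statistic = stat, p_value = p, average_ranks = R, N = N, k = k)
}

## critical values q_alpha of the studentized range statistic divided by
## sqrt(2), for the two-tailed Nemenyi test (Demsar 2006, Table 5)
.nemenyi_q <- list(
  "0.05" = c(`2` = 1.960, `3` = 2.343, `4` = 2.569, `5` = 2.728,
             `6` = 2.850, `7` = 2.949, `8` = 3.031, `9` = 3.102,
             `10` = 3.164),
  "0.1"  = c(`2` = 1.645, `3` = 2.052, `4` = 2.291, `5` = 2.459,
             `6` = 2.589, `7` = 2.693, `8` = 2.780, `9` = 2.855,
             `10` = 2.920))

#' Nemenyi critical difference
#'
#' Two methods among `k` compared on `N` datasets differ significantly at
#' level `alpha` when their average ranks differ by more than
#' `CD = q_alpha * sqrt(k (k+1) / (6 N))`, with `q_alpha` the tabulated
#' two-tailed studentized-range constant.
#'
#' @param k Number of methods (2..10, the tabulated range).
#' @param N Number of datasets (`>= 1`).
#' @param alpha Significance level, 0.05 or 0.10.
#' @return Positive scalar critical difference.
#' @export
nemenyi_critical_difference <- function(k, N, alpha = 0.05) {
  k <- as.integer(k); N <- as.integer(N)
  if (N < 1L) stop("`N` must be >= 1", call. = FALSE)
  key <- as.character(alpha)
  if (!key %in% names(.nemenyi_q))
    stop("`alpha` must be 0.05 or 0.10", call. = FALSE)
  qtab <- .nemenyi_q[[key]]
  if (!as.character(k) %in% names(qtab))
    stop("`k` must lie in 2..10 (tabulated range)", call. = FALSE)
  unname(qtab[as.character(k)] * sqrt(k * (k + 1) / (6 * N)))
}
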