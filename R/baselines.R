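#' Median-threshold baseline (MT)
#'
#' Dichotomizes each experiment at its across-gene median (or mean):
#' a_ij = 1 when eps_ij >= M_j, else 0. The mean variant matches the
#' default threshold statistic of penalty-based model-integration
#' tools; with the typical within-experiment symmetry of log
#' expression the two are nearly identical.
#'
#' @param compendium an [expression_compendium()] (or plain matrix,
#'   genes x experiments).
#' @param statistic `"median"` (default) or `"mean"`.
#' @return activity matrix with values in \{0, 1\}, same dimnames.
#' @export
median_threshold <- function(compendium, statistic = c("median", "mean")) {
  statistic <- match.arg(statistic)
  x <- unclass(compendium)
  thr <- apply(x, 2, if (statistic == "median") stats::median else mean)
  a <- (sweep(x, 2, thr, `>=`)) * 1
  dimnames(a) <- dimnames(x)
  a
}

#' Trichotomous-threshold baseline (TT)
#'
#' Trichotomizes each experiment with an uncertain middle band:
#' a_ij = 0 below the per-experiment `low_pct` percentile, 0.5 in
#' \[P_low, P_high), and 1 at or above the `high_pct` percentile, so
#' the three bins partition the line. Percentiles use the linear
#' interpolation of the empirical CDF (`stats::quantile` type 7).
#'
#' @inheritParams median_threshold
#' @param low_pct,high_pct percentile bounds of the uncertain region
#'   (defaults 40 and 60); equal bounds of 50 reduce to MT.
#' @return activity matrix with values in \{0, 0.5, 1\}.
#' @export
trichotomous_threshold <- function(compendium, low_pct = 40, high_pct = 60) {
  stopifnot(low_pct <= high_pct)
  x <- unclass(compendium)
  a <- x
  for (j in seq_len(ncol(x))) {
    q <- stats::quantile(x[, j], c(low_pct, high_pct) / 100, names = FALSE)
    a[, j] <- ifelse(x[, j] >= q[2], 1, ifelse(x[, j] >= q[1], 0.5, 0))
  }
  a
}

#' Rank-based baseline (RB)
#'
#' Continuous analog of MT: a_ij = rank(eps_ij) / m within each
#' experiment (ascending ranks, average ranks for ties, m genes), so
#' the highest expression in an experiment receives a_ij = 1 and
#' confidence decreases monotonically with expression.
#'
#' @inheritParams median_threshold
#' @return activity matrix with values in (0, 1\].
#' @export
rank_based <- function(compendium) {
  x <- unclass(compendium)
  a <- apply(x, 2, function(col) rank(col, ties.method = "average")) / nrow(x)
  dimnames(a) <- dimnames(x)
  a
}
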