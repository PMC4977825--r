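# Equal-variance Gaussian mixture EM used by the BIC screen. Restarts
# use k-means++-style initial centers; the best log-likelihood wins.
# Univariate x: plain vector. Multivariate (operon) x: p x n matrix
# with diagonal per-gene covariance shared between states.

.loglik1 <- function(x) {
  if (is.matrix(x)) {
    sum(vapply(seq_len(nrow(x)), function(g) {
      mu <- mean(x[g, ]); s <- sqrt(mean((x[g, ] - mu)^2))
      sum(stats::dnorm(x[g, ], mu, s, log = TRUE))
    }, numeric(1)))
  } else {
    mu <- mean(x); s <- sqrt(mean((x - mu)^2))
    sum(stats::dnorm(x, mu, s, log = TRUE))
  }
}

.em2 <- function(x, restarts = 5, max_iter = 200, tol = 1e-8) {
  xm <- rbind(x)                      # p x n; p = 1 for a single gene
  p <- nrow(xm); n <- ncol(xm)
  best <- -Inf
  for (r in seq_len(restarts)) {
    # k-means++-style init on experiment columns
    i1 <- sample.int(n, 1)
    d2 <- colSums((xm - xm[, i1])^2)
    if (all(d2 == 0)) return(-Inf)
    i2 <- sample.int(n, 1, prob = d2 / sum(d2))
    mu0 <- xm[, i1]; mu1 <- xm[, i2]
    if (sum(mu0) > sum(mu1)) { tmp <- mu0; mu0 <- mu1; mu1 <- tmp }
    sig <- apply(xm, 1, stats::sd); sig[sig == 0] <- 1e-6
    pi_ <- 0.5
    ll_old <- -Inf; ll <- -Inf
    for (it in seq_len(max_iter)) {
      l0 <- colSums(matrix(stats::dnorm(xm, mu0, sig, log = TRUE), p)) +
        log1p(-pi_)
      l1 <- colSums(matrix(stats::dnorm(xm, mu1, sig, log = TRUE), p)) +
        log(pi_)
      m <- pmax(l0, l1)
      ll <- sum(m + log(exp(l0 - m) + exp(l1 - m)))
      z <- 1 / (1 + exp(l0 - l1))
      w1 <- sum(z); w0 <- n - w1
      if (w1 < 1e-10 || w0 < 1e-10) break
      pi_ <- w1 / n
      mu0 <- as.numeric(xm %*% (1 - z)) / w0
      mu1 <- as.numeric(xm %*% z) / w1
      sig <- sqrt((((xm - mu0)^2) %*% (1 - z) + ((xm - mu1)^2) %*% z) / n)
      sig <- pmax(as.numeric(sig), 1e-8)
      if (is.finite(ll) && abs(ll - ll_old) < tol) break
      ll_old <- ll
    }
    if (is.finite(ll) && ll > best) best <- ll
  }
  best
}

#' BIC screen: one-component vs two-component mixture
#'
#' Some genes or operons never change activity state across the
#' compendium, making a two-component mixture invalid. This screen fits
#' equal-variance Gaussian mixtures with 1 and 2 components by maximum
#' likelihood (EM with 5 k-means++-style restarts; diagonal per-gene
#' covariance for operon blocks) and compares
#' BIC = 2 loglik - d log n (higher is better; d = 2p for one
#' component, 3p + 1 for two). The one-component model is called only
#' when its BIC beats the two-component BIC by at least `margin`
#' points (default 12, a conventional "very strong evidence"
#' threshold); plain best-BIC selection is the `margin = -Inf` limit.
#' The screen is deterministic: EM restarts use a seed derived from
#' `seed` and `unit`, and the caller's RNG state is left untouched.
#'
#' @param x numeric vector (one gene) or p x n matrix (operon block,
#'   genes in rows).
#' @param margin BIC margin required to prefer the 1-component model.
#' @param min_n minimum number of experiments required (default 10).
#' @param unit identifier carried into the returned call (also keys
#'   the EM restart seed).
#' @param restarts number of EM restarts.
#' @param seed base seed for the EM restarts.
#' @return a list with class `"component_call"`: `unit`, `n_components`
#'   (1 or 2), `bic1`, `bic2`, and the one-component fitted `mean` and
#'   `sd` (maximum-likelihood; per-gene vectors for a block).
#' @export
bic_screen <- function(x, margin = 12, min_n = 10, unit = "unit",
                       restarts = 5, seed = 1) {
  is_block <- is.matrix(x) && nrow(x) > 1
  n <- if (is_block) ncol(x) else length(x)
  p <- if (is_block) nrow(x) else 1L
  if (n < min_n) stop("need at least ", min_n, " experiments to screen")

  out <- structure(list(
    unit = unit, n_components = 1L, bic1 = NA_real_, bic2 = NA_real_,
    mean = if (is_block) rowMeans(x) else mean(x),
    sd = if (is_block) sqrt(rowMeans((x - rowMeans(x))^2))
         else sqrt(mean((x - mean(x))^2))), class = "component_call")

  degenerate <- if (is_block) any(apply(x, 1, stats::var) == 0)
                else stats::var(as.numeric(x)) == 0
  if (degenerate) {
    warning("degenerate (zero-variance) data; 1-component call",
            call. = FALSE)
    return(out)
  }

  # run EM under a derived seed without disturbing the caller's RNG
  rs <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(rs)) assign(".Random.seed", rs, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(derive_seed(seed, unit))

  ll1 <- .loglik1(x)
  ll2 <- .em2(if (is_block) x else as.numeric(x), restarts = restarts)
  bic1 <- 2 * ll1 - (2 * p) * log(n)
  bic2 <- 2 * ll2 - (3 * p + 1) * log(n)
  out$bic1 <- bic1; out$bic2 <- bic2
  out$n_components <- if (!is.finite(bic2) || bic1 - bic2 >= margin) 1L else 2L
  out
}

#' Find genes with similar fitted mixture parameters
#'
#' A fitted 2-component gene is "similar" to a single-component gene
#' with sample mean `x_bar` and sd `s` when either of its state means
#' lies within `tol` of `x_bar` while its shared within-state sd lies
#' within `tol` of `s` (inclusive bounds):
#' (mu0 in x_bar +/- tol and sigma in s +/- tol) or
#' (mu1 in x_bar +/- tol and sigma in s +/- tol).
#'
#' @param x_bar,s single-component fitted mean and sd of the target.
#' @param fits named list of 2-component [mixture_model()]s.
#' @param tol similarity half-width (default 0.1).
#' @return character vector of similar gene ids (possibly empty).
#' @export
find_similar_genes <- function(x_bar, s, fits, tol = 0.1) {
  if (length(fits) == 0) return(character(0))
  ok <- vapply(fits, function(m) {
    sd_ok <- abs(m$sigma[1] - s) <= tol
    sd_ok && (abs(m$mu0[1] - x_bar) <= tol || abs(m$mu1[1] - x_bar) <= tol)
  }, logical(1))
  names(fits)[ok]
}

#' Impute activity for a single-component gene
#'
#' Computes the activity a_j the gene would receive if its expression
#' row had come from each similar gene's fitted mixture (the analytic
#' responsibility under that model), then averages the resulting
#' vectors elementwise. With no similar genes, a_j = 0.5 everywhere.
#'
#' @param eps_row numeric vector of log expression.
#' @param similar list of fitted 2-component [mixture_model()]s.
#' @return numeric vector of imputed a_j in \[0, 1\].
#' @export
impute_activity <- function(eps_row, similar) {
  if (length(similar) == 0) return(rep(0.5, length(eps_row)))
  avec <- vapply(similar, function(m) responsibilities(eps_row, m),
                 numeric(length(eps_row)))
  rowMeans(matrix(avec, nrow = length(eps_row)))
}

#' Impute activity for a single-component operon
#'
#' Each gene of the operon is imputed separately with
#' [impute_activity()]; the per-gene vectors are then averaged so that
#' every gene of the operon receives identical a_j. The operon is
#' declared always-active (pi_hat = 1) when the mean imputed a exceeds
#' 0.5, always-inactive (pi_hat = 0) below 0.5, and unresolved
#' (pi_hat = NA) at exactly 0.5.
#'
#' @param block p x n matrix of the operon's log expression.
#' @param similar_per_gene list of length p; element g is the list of
#'   fitted models similar to gene g.
#' @return list with `a` (p x n matrix, identical rows) and `pi_hat`.
#' @export
impute_operon <- function(block, similar_per_gene) {
  block <- rbind(block)
  p <- nrow(block); n <- ncol(block)
  stopifnot(length(similar_per_gene) == p)
  per_gene <- vapply(seq_len(p), function(g)
    impute_activity(block[g, ], similar_per_gene[[g]]), numeric(n))
  a_row <- rowMeans(matrix(per_gene, nrow = n))
  a <- matrix(rep(a_row, each = p), p, n,
              dimnames = list(rownames(block), colnames(block)))
  m <- mean(a_row)
  pi_hat <- if (m > 0.5) 1 else if (m < 0.5) 0 else NA_real_
  list(a = a, pi_hat = pi_hat)
}
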