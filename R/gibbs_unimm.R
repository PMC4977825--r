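#' Conditional probability that expression values come from the active state
#'
#' For a two-component equal-variance Gaussian mixture, the
#' responsibility of the active component for each observation:
#' b_j = pi f1(e_j) / (pi f1(e_j) + (1 - pi) f0(e_j)).
#' Computed in log space (logistic of the log-odds) to avoid underflow.
#'
#' @param eps_row numeric vector of log expression values.
#' @param model a 2-component [mixture_model()].
#' @return numeric vector of responsibilities in \[0, 1\].
#' @export
responsibilities <- function(eps_row, model) {
  if (model$n_components != 2L) stop("model must have 2 components")
  if (any(model$sigma <= 0)) stop("sigma must be positive")
  lf1 <- stats::dnorm(eps_row, model$mu1, model$sigma, log = TRUE)
  lf0 <- stats::dnorm(eps_row, model$mu0, model$sigma, log = TRUE)
  stats::plogis(log(model$pi) - log1p(-model$pi) + lf1 - lf0)
}

#' Draw binary activity indicators
#'
#' One independent Bernoulli(b_j) draw per experiment.
#'
#' @param b vector of responsibilities in \[0, 1\].
#' @return integer vector of 0/1 indicators.
#' @export
draw_indicators <- function(b) {
  stopifnot(all(b >= 0), all(b <= 1))
  as.integer(stats::runif(length(b)) < b)
}

#' Sample a state mean from its conjugate normal posterior
#'
#' With prior N(prior_mean, prior_var) and n_c observations of mean
#' x_bar at known sigma, the posterior is N(m*, v*) with
#' v* = (n_c / sigma^2 + 1 / prior_var)^-1 and
#' m* = v* (prior_mean / prior_var + n_c x_bar / sigma^2).
#' An empty cluster (n_c = 0) draws from the prior.
#'
#' @param n_c size of the assigned cluster.
#' @param x_bar mean of the cluster's expression values (ignored when
#'   `n_c` is 0).
#' @param sigma current within-state standard deviation.
#' @param prior_mean,prior_var normal prior on the mean.
#' @return one draw of mu.
#' @export
update_mu <- function(n_c, x_bar, sigma, prior_mean, prior_var = 3) {
  stopifnot(sigma > 0, prior_var > 0)
  if (n_c == 0) x_bar <- 0  # data term vanishes
  v <- 1 / (n_c / sigma^2 + 1 / prior_var)
  m <- v * (prior_mean / prior_var + n_c * x_bar / sigma^2)
  stats::rnorm(1, m, sqrt(v))
}

#' Sample the shared within-state variance (returned as sigma)
#'
#' The univariate inverse-Wishart posterior IW(Psi + SS, nu + n) is an
#' inverse-gamma on the variance with shape (nu + n) / 2 and scale
#' (Psi + SS) / 2, where SS is the total residual sum of squares
#' around the currently assigned state means over all n experiments.
#'
#' @param residual_ss residual sum of squares, >= 0.
#' @param n total number of experiments contributing residuals.
#' @param prior a [prior_config()] supplying `iw_scale` (Psi) and
#'   `iw_df` (nu).
#' @return one draw of sigma (standard deviation).
#' @export
update_sigma <- function(residual_ss, n, prior = prior_config()) {
  stopifnot(residual_ss >= 0, n >= 0)
  v <- 1 / stats::rgamma(1, shape = (prior$iw_df + n) / 2,
                         rate = (prior$iw_scale + residual_ss) / 2)
  sqrt(v)
}

#' Sample the mixing proportion from its Beta posterior
#'
#' pi ~ Beta(alpha + |C_active|, beta + |C_inactive|).
#'
#' @param n_active,n_inactive cluster sizes.
#' @param prior a [prior_config()] supplying `beta_a`, `beta_b`.
#' @return one draw of pi.
#' @export
update_pi <- function(n_active, n_inactive, prior = prior_config()) {
  stopifnot(n_active >= 0, n_inactive >= 0)
  stats::rbeta(1, prior$beta_a + n_active, prior$beta_b + n_inactive)
}

#' Univariate mixture-model Gibbs sampler (UniMM) for one gene
#'
#' Estimates the posterior probability a_j that the gene is active in
#' each experiment from its row of log expression values, under the
#' two-component equal-variance Gaussian mixture. The chain starts at
#' mu0 = 8, mu1 = 9, sigma = 1, pi = 0.5 and alternates: compute
#' responsibilities from the current parameters; draw binary activity
#' indicators; redraw mu0, mu1, sigma, pi from their conjugate
#' posteriors given the indicator assignment. Whenever a draw violates
#' the label convention mu0 <= mu1, labels are swapped (indicators
#' complemented, pi reflected). a_j is the mean of the post-burn-in
#' indicators; the returned fit holds post-burn-in posterior means.
#'
#' @param eps_row numeric vector of log expression (length >= 2).
#' @param prior a [prior_config()].
#' @param cfg a [gibbs_config()].
#' @param id unit identifier used (with `cfg$seed`) to derive this
#'   gene's RNG seed; results are then invariant to compendium order.
#' @param update_params if FALSE the parameters stay fixed at their
#'   initial values and only indicators are drawn (diagnostic mode; the
#'   long-run a_j then equals the analytic responsibility).
#' @param init optional named list overriding the initial values
#'   (`mu0`, `mu1`, `sigma`, `pi`).
#' @param trace if TRUE, also return a K x 4 matrix of parameter draws.
#' @return list with `a` (vector of a_j), `fit` (a [mixture_model()]),
#'   and optionally `trace`.
#' @export
run_unimm <- function(eps_row, prior = prior_config(), cfg = gibbs_config(),
                      id = "gene", update_params = TRUE, init = NULL,
                      trace = FALSE) {
  eps_row <- as.numeric(eps_row)
  n <- length(eps_row)
  if (n < 2) stop("need at least 2 experiments")
  if (any(!is.finite(eps_row))) stop("non-finite expression values")
  set_unit_seed(cfg, id)

  mu0 <- 8; mu1 <- 9; sigma <- 1; pi <- 0.5
  for (nm in names(init)) assign(nm, init[[nm]])
  K <- cfg$iterations; b <- cfg$burn_in

  acc <- numeric(n)
  sum_mu0 <- sum_mu1 <- sum_sigma <- sum_pi <- 0
  tr <- if (trace) matrix(NA_real_, K, 4,
                          dimnames = list(NULL, c("mu0", "mu1", "sigma", "pi")))

  for (k in seq_len(K)) {
    bk <- responsibilities(eps_row, mixture_model(pi, mu0, mu1, sigma))
    bk <- pmin(pmax(bk, 1e-12), 1 - 1e-12)
    I <- draw_indicators(bk)

    if (update_params) {
      act <- I == 1L
      n1 <- sum(act); n0 <- n - n1
      x1 <- if (n1) mean(eps_row[act]) else 0
      x0 <- if (n0) mean(eps_row[!act]) else 0
      mu0 <- update_mu(n0, x0, sigma, prior$mu0_mean, prior$mu_var)
      mu1 <- update_mu(n1, x1, sigma, prior$mu1_mean, prior$mu_var)
      ss <- sum((eps_row[act] - mu1)^2) + sum((eps_row[!act] - mu0)^2)
      sigma <- update_sigma(ss, n, prior)
      pi <- update_pi(n1, n0, prior)
      if (mu0 > mu1) {  # relabel: keep the inactive state as the lower mean
        tmp <- mu0; mu0 <- mu1; mu1 <- tmp
        pi <- 1 - pi
        I <- 1L - I
      }
    }

    if (k > b) {
      acc <- acc + I
      sum_mu0 <- sum_mu0 + mu0; sum_mu1 <- sum_mu1 + mu1
      sum_sigma <- sum_sigma + sigma; sum_pi <- sum_pi + pi
    }
    if (trace) tr[k, ] <- c(mu0, mu1, sigma, pi)
  }

  w <- K - b
  fit <- mixture_model(sum_pi / w, sum_mu0 / w, sum_mu1 / w, sum_sigma / w)
  out <- list(a = acc / w, fit = fit)
  if (trace) out$trace <- tr
  out
}

#' Run UniMM over every gene of a compendium
#'
#' @param compendium an [expression_compendium()].
#' @inheritParams run_unimm
#' @return list with `a` (activity matrix, same dimnames as the
#'   compendium) and `fits` (named list of per-gene [mixture_model()]s).
#' @export
unimm_compendium <- function(compendium, prior = prior_config(),
                             cfg = gibbs_config()) {
  genes <- rownames(compendium)
  a <- matrix(NA_real_, nrow(compendium), ncol(compendium),
              dimnames = dimnames(compendium))
  fits <- vector("list", length(genes)); names(fits) <- genes
  for (g in genes) {
    res <- run_unimm(compendium[g, ], prior, cfg, id = g)
    a[g, ] <- res$a
    fits[[g]] <- res$fit
  }
  list(a = a, fits = fits)
}
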