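#' Shared-state responsibilities for an operon block
#'
#' For p genes of an operon observed across n experiments, the
#' probability that experiment j is in the active state under the
#' multivariate diagonal-covariance mixture. With zero within-state
#' covariance the joint density factorizes, so the log-odds is the sum
#' of per-gene log density ratios plus the mixing log-odds.
#'
#' @param block p x n numeric matrix (operon genes by experiments).
#' @param model a 2-component [mixture_model()] with per-gene vectors
#'   `mu0`, `mu1`, `sigma` (length p) and scalar `pi`.
#' @return numeric vector of length n of responsibilities in \[0, 1\].
#' @export
operon_responsibilities <- function(block, model) {
  block <- rbind(block)
  p <- nrow(block)
  stopifnot(length(model$mu0) == p, all(model$sigma > 0))
  lratio <- stats::dnorm(block, model$mu1, model$sigma, log = TRUE) -
    stats::dnorm(block, model$mu0, model$sigma, log = TRUE)
  stats::plogis(log(model$pi) - log1p(-model$pi) + colSums(lratio))
}

#' Multivariate mixture-model Gibbs sampler (MultiMM) for one operon
#'
#' All p genes of an operon are assumed co-regulated: a single binary
#' activity indicator per experiment is shared by every gene, so the
#' returned activity matrix has identical rows. Priors: per-gene state
#' means N(8, var 3) and N(9, var 3); shared diagonal within-state
#' covariance with an inverse-Wishart(df = p + 2, identity scale)
#' prior, realized per gene as inverse-gamma(shape = (p + 2 + n) / 2,
#' scale = (1 + SS_g) / 2); pi ~ Beta(5, 5). Label switching is
#' resolved on the sign of mean(mu1 - mu0).
#'
#' @param block p x n matrix of log expression for the operon's genes
#'   (rownames = gene ids), or a numeric vector for p = 1.
#' @param prior a [prior_config()]; `iw_df`/`iw_scale` default to the
#'   multivariate convention p + 2 / identity unless `iw_df_override`
#'   is given.
#' @param cfg a [gibbs_config()].
#' @param id operon identifier used for seed derivation.
#' @param iw_df_override optional inverse-Wishart df replacing p + 2
#'   (used to align the p = 1 case with the univariate sampler).
#' @return list with `a` (p x n matrix, identical rows), `fit` (a
#'   multivariate [mixture_model()]).
#' @export
run_multimm <- function(block, prior = prior_config(), cfg = gibbs_config(),
                        id = "operon", iw_df_override = NULL) {
  block <- rbind(block)
  p <- nrow(block); n <- ncol(block)
  if (n < 2) stop("need at least 2 experiments")
  if (any(!is.finite(block))) stop("non-finite expression values")
  set_unit_seed(cfg, id)

  iw_df <- if (is.null(iw_df_override)) p + 2 else iw_df_override
  iw_scale <- if (is.null(iw_df_override)) 1 else prior$iw_scale

  mu0 <- rep(prior$mu0_mean, p); mu1 <- rep(prior$mu1_mean, p)
  sigma <- rep(1, p); pi <- 0.5
  K <- cfg$iterations; b <- cfg$burn_in

  acc <- numeric(n)
  sum_mu0 <- sum_mu1 <- sum_sigma <- numeric(p); sum_pi <- 0

  for (k in seq_len(K)) {
    bk <- operon_responsibilities(block, mixture_model(pi, mu0, mu1, sigma))
    bk <- pmin(pmax(bk, 1e-12), 1 - 1e-12)
    I <- draw_indicators(bk)

    act <- I == 1L
    n1 <- sum(act); n0 <- n - n1
    for (g in seq_len(p)) {
      x1 <- if (n1) mean(block[g, act]) else 0
      x0 <- if (n0) mean(block[g, !act]) else 0
      mu0[g] <- update_mu(n0, x0, sigma[g], prior$mu0_mean, prior$mu_var)
      mu1[g] <- update_mu(n1, x1, sigma[g], prior$mu1_mean, prior$mu_var)
      ss_g <- sum((block[g, act] - mu1[g])^2) + sum((block[g, !act] - mu0[g])^2)
      v <- 1 / stats::rgamma(1, shape = (iw_df + n) / 2,
                             rate = (iw_scale + ss_g) / 2)
      sigma[g] <- sqrt(v)
    }
    pi <- update_pi(n1, n0, prior)
    if (mean(mu1 - mu0) < 0) {
      tmp <- mu0; mu0 <- mu1; mu1 <- tmp
      pi <- 1 - pi
      I <- 1L - I
    }

    if (k > b) {
      acc <- acc + I
      sum_mu0 <- sum_mu0 + mu0; sum_mu1 <- sum_mu1 + mu1
      sum_sigma <- sum_sigma + sigma; sum_pi <- sum_pi + pi
    }
  }

  w <- K - b
  a_row <- acc / w
  a <- matrix(rep(a_row, each = p), p, n,
              dimnames = list(rownames(block), colnames(block)))
  fit <- mixture_model(sum_pi / w, sum_mu0 / w, sum_mu1 / w, sum_sigma / w)
  list(a = a, fit = fit)
}

#' Run MultiMM over every operon of a compendium
#'
#' Operon genes missing from the compendium are dropped with a warning
#' (via [complete_operon_map()]); unmapped genes become singleton
#' operons and are fitted as p = 1 blocks.
#'
#' @param compendium an [expression_compendium()].
#' @param operons an [operon_map()] or NULL (all singletons).
#' @inheritParams run_multimm
#' @return list with `a` (activity matrix over all genes) and `fits`
#'   (named list of per-operon [mixture_model()]s).
#' @export
multimm_compendium <- function(compendium, operons = NULL,
                               prior = prior_config(), cfg = gibbs_config()) {
  operons <- complete_operon_map(operons, compendium)
  a <- matrix(NA_real_, nrow(compendium), ncol(compendium),
              dimnames = dimnames(compendium))
  fits <- vector("list", length(operons)); names(fits) <- names(operons)
  for (op in names(operons)) {
    genes <- operons[[op]]
    res <- run_multimm(compendium[genes, , drop = FALSE], prior, cfg, id = op)
    a[genes, ] <- res$a
    fits[[op]] <- res$fit
  }
  list(a = a, fits = fits)
}
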