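#' Build a simulation design for a ground-truth compendium
#'
#' Assigns each operon a component flag, a mixing proportion and
#' per-gene state parameters, emulating a large bacterial expression
#' compendium. Defaults: each operon is single-component (never
#' changes state) with probability 0.263, and single-component operons
#' are always-active or always-inactive with equal probability;
#' two-component operons draw pi ~ Unif(0.2, 0.8) ("Unif" mode) or
#' take fitted values ("Fit" mode). Per-gene parameters come either
#' from supplied fitted models (Fit) or from stand-in sampling
#' distributions calibrated to fitted quartiles reported for a real
#' E. coli compendium (inactive mean ~ N(8.1, sd 0.8); active-minus-
#' inactive separation ~ N(1.1, sd 0.7) truncated at 0.3; within-state
#' sd ~ Unif(0.3, 0.6)). Operon sizes default to a categorical
#' distribution with ~71.6% singletons.
#'
#' @param n_operons number of operons.
#' @param n_experiments number of experiments (the motivating real
#'   compendium has 907).
#' @param single_component_fraction probability an operon is
#'   single-component (default 0.263).
#' @param pi_mode `"Unif"` (pi ~ Unif(`pi_bounds`)) or `"Fit"` (pi and
#'   per-gene parameters taken from `fits`).
#' @param pi_bounds bounds of the uniform pi draw (default 0.2, 0.8).
#' @param operon_sizes,size_probs categorical operon-size
#'   distribution (defaults: sizes 1:5 with probabilities 0.716, 0.14,
#'   0.08, 0.04, 0.024).
#' @param fits named list of multivariate [mixture_model()]s (one per
#'   operon, vector parameters of the operon's size), required for
#'   `pi_mode = "Fit"`; operon sizes then follow the fits.
#' @param mu0_fun,delta_fun,sigma_fun override the stand-in parameter
#'   samplers; each takes a count and returns that many draws.
#' @param seed integer RNG seed.
#' @return a list with class `"sim_design"`: per-operon entries
#'   `genes`, `n_components`, `pi`, `active` (single-component state),
#'   `mu0`, `mu1`, `sigma`, plus `n_experiments` and `seed`.
#' @export
build_sim_design <- function(n_operons = 100,
                             n_experiments = 907,
                             single_component_fraction = 0.263,
                             pi_mode = c("Unif", "Fit"),
                             pi_bounds = c(0.2, 0.8),
                             operon_sizes = 1:5,
                             size_probs = c(0.716, 0.14, 0.08, 0.04, 0.024),
                             fits = NULL,
                             mu0_fun = NULL, delta_fun = NULL, sigma_fun = NULL,
                             seed = NULL) {
  pi_mode <- match.arg(pi_mode)
  stopifnot(single_component_fraction >= 0, single_component_fraction <= 1,
            length(pi_bounds) == 2, pi_bounds[1] > 0, pi_bounds[2] < 1,
            pi_bounds[1] <= pi_bounds[2],
            length(operon_sizes) == length(size_probs))
  if (pi_mode == "Fit" && is.null(fits))
    stop("pi_mode = 'Fit' requires fitted models")
  if (!is.null(seed)) set.seed(seed)

  if (is.null(mu0_fun)) mu0_fun <- function(k) stats::rnorm(k, 8.1, 0.8)
  if (is.null(delta_fun)) delta_fun <- function(k) {
    # truncated normal (min 0.3) via inverse-CDF
    lo <- stats::pnorm((0.3 - 1.1) / 0.7)
    1.1 + 0.7 * stats::qnorm(stats::runif(k, lo, 1))
  }
  if (is.null(sigma_fun)) sigma_fun <- function(k) stats::runif(k, 0.3, 0.6)

  if (pi_mode == "Fit") n_operons <- length(fits)
  operons <- vector("list", n_operons)
  gene_counter <- 0
  for (r in seq_len(n_operons)) {
    if (pi_mode == "Fit") {
      f <- fits[[r]]
      p <- length(f$mu0)
      mu0 <- f$mu0; mu1 <- f$mu1; sig <- f$sigma; pi_r <- f$pi
    } else {
      p <- operon_sizes[sample.int(length(operon_sizes), 1, prob = size_probs)]
      mu0 <- mu0_fun(p); mu1 <- mu0 + delta_fun(p); sig <- sigma_fun(p)
      pi_r <- stats::runif(1, pi_bounds[1], pi_bounds[2])
    }
    single <- stats::runif(1) < single_component_fraction
    operons[[r]] <- list(
      genes = sprintf("g%04d", gene_counter + seq_len(p)),
      n_components = if (single) 1L else 2L,
      pi = pi_r,
      active = if (single) stats::runif(1) < 0.5 else NA,
      mu0 = mu0, mu1 = mu1, sigma = sig)
    gene_counter <- gene_counter + p
  }
  names(operons) <- sprintf("op%03d", seq_len(n_operons))
  structure(list(operons = operons, n_experiments = n_experiments,
                 seed = seed),
            class = "sim_design")
}

#' Simulate a ground-truth expression compendium
#'
#' For each two-component operon, round(n * pi) experiments are chosen
#' uniformly at random as active (all genes of the operon share the
#' state in each experiment); expression is drawn from the per-gene
#' state Gaussian. Single-component operons draw every experiment from
#' their one state. Returns the compendium together with the true
#' activity matrix and the generating design.
#'
#' @param design a [build_sim_design()] result.
#' @param seed optional RNG seed (defaults to the design's seed + 1).
#' @return a list with class `"sim_truth"`: `compendium` (an
#'   [expression_compendium()]), `alpha` (0/1 truth matrix, same
#'   dimnames), `operon_map` (an [operon_map()]), `design`.
#' @export
simulate_compendium <- function(design, seed = NULL) {
  stopifnot(inherits(design, "sim_design"))
  if (is.null(seed) && !is.null(design$seed)) seed <- design$seed + 1
  if (!is.null(seed)) set.seed(seed)
  n <- design$n_experiments
  exps <- sprintf("e%04d", seq_len(n))
  genes <- unlist(lapply(design$operons, `[[`, "genes"), use.names = FALSE)

  eps <- matrix(NA_real_, length(genes), n, dimnames = list(genes, exps))
  alpha <- matrix(NA_integer_, length(genes), n, dimnames = list(genes, exps))

  for (op in design$operons) {
    state <- integer(n)
    if (op$n_components == 2L) {
      n_active <- round(n * op$pi)
      state[sample.int(n, n_active)] <- 1L
    } else if (isTRUE(op$active)) {
      state[] <- 1L
    }
    for (g in seq_along(op$genes)) {
      mu <- ifelse(state == 1L, op$mu1[g], op$mu0[g])
      eps[op$genes[g], ] <- stats::rnorm(n, mu, op$sigma[g])
      alpha[op$genes[g], ] <- state
    }
  }
  omap <- operon_map(lapply(design$operons, `[[`, "genes"))
  structure(list(compendium = expression_compendium(eps), alpha = alpha,
                 operon_map = omap, design = design),
            class = "sim_truth")
}
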