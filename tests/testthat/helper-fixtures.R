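# In-code fixtures shared across test files.

# One gene's expression row drawn from a two-state Gaussian with a
# fixed active/inactive assignment (first n0 experiments inactive).
two_state_row <- function(n0 = 100, n1 = 100, mu0 = 7, mu1 = 10,
                          sigma = 0.3, seed = 42) {
  set.seed(seed)
  list(eps = c(rnorm(n0, mu0, sigma), rnorm(n1, mu1, sigma)),
       alpha = rep(c(0L, 1L), c(n0, n1)))
}

# Small labelled compendium matrix.
toy_compendium <- function(m = 5, n = 8, seed = 7) {
  set.seed(seed)
  x <- matrix(rnorm(m * n, 9, 1.5), m, n,
              dimnames = list(paste0("g", seq_len(m)),
                              paste0("e", seq_len(n))))
  expression_compendium(x)
}

# Random fitted-model pool for similarity / imputation tests.
random_model_pool <- function(k = 50, seed = 11) {
  set.seed(seed)
  fits <- lapply(seq_len(k), function(i)
    mixture_model(runif(1, .2, .8), runif(1, 6, 9),
                  runif(1, 9, 12), runif(1, .2, .8)))
  names(fits) <- paste0("g", seq_len(k))
  fits
}
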