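#' Construct an expression compendium
#'
#' An expression compendium is a genes x experiments matrix of
#' background-corrected, normalized, log-scale expression values
#' (RMA-like units, typically between 4 and 16). Rows are genes,
#' columns are experiments; both must carry unique identifiers.
#'
#' @param values numeric matrix, rows = genes, columns = experiments,
#'   with unique rownames (gene ids) and colnames (experiment ids).
#' @return the matrix with class `"expression_compendium"` prepended,
#'   after validation.
#' @export
expression_compendium <- function(values) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  obj <- structure(values, class = c("expression_compendium", "matrix", "array"))
  validate_compendium(obj)
  obj
}

#' Validate an expression compendium
#'
#' Hard errors on structural problems (missing/non-finite values,
#' missing or duplicated identifiers, fewer than 2 experiments);
#' returns character warnings for values outside the plausible
#' log-expression range \[0, 20\].
#'
#' @param compendium matrix of log expression, genes x experiments.
#' @return invisibly, a character vector of warnings (also emitted
#'   via [warning()]).
#' @export
validate_compendium <- function(compendium) {
  x <- unclass(compendium)
  if (!is.matrix(x) || !is.numeric(x))
    stop("compendium must be a numeric matrix (genes x experiments)")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("compendium must have gene rownames and experiment colnames")
  if (anyDuplicated(rownames(x)))
    stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(x)))
    stop("duplicate experiment identifiers")
  if (ncol(x) < 2)
    stop("compendium must contain at least 2 experiments")
  if (anyNA(x) || any(!is.finite(x)))
    stop("compendium contains missing or non-finite values")
  warnings <- character(0)
  if (any(x < 0 | x > 20)) {
    warnings <- c(warnings, sprintf(
      "%d value(s) outside the plausible log-expression range [0, 20]",
      sum(x < 0 | x > 20)))
  }
  for (w in warnings) warning(w, call. = FALSE)
  invisible(warnings)
}

#' Construct an operon map
#'
#' A partition of genes into operons. Genes of the compendium that are
#' not listed are treated as single-gene operons when the map is
#' completed against a compendium with [complete_operon_map()].
#'
#' @param operons named list; each element a nonempty character vector
#'   of gene identifiers, names are operon identifiers.
#' @return the list with class `"operon_map"`.
#' @export
operon_map <- function(operons) {
  if (!is.list(operons) || is.null(names(operons)) || any(names(operons) == ""))
    stop("operons must be a named list of gene id vectors")
  if (anyDuplicated(names(operons)))
    stop("duplicate operon identifiers")
  operons <- lapply(operons, as.character)
  if (any(lengths(operons) == 0))
    stop("operon with empty gene list")
  genes <- unlist(operons, use.names = FALSE)
  if (anyDuplicated(genes))
    stop("gene assigned to more than one operon: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  structure(operons, class = "operon_map")
}

#' Complete an operon map against a compendium
#'
#' Drops mapped genes absent from the compendium (with a warning),
#' removes operons left empty, and adds every unmapped compendium gene
#' as a singleton operon named after the gene.
#'
#' @param map an [operon_map()] (or NULL for all-singleton).
#' @param compendium an [expression_compendium()].
#' @return an `operon_map` whose gene union equals the compendium genes.
#' @export
complete_operon_map <- function(map, compendium) {
  genes <- rownames(compendium)
  if (is.null(map)) map <- operon_map(stats::setNames(list(), character(0)))
  ops <- unclass(map)
  kept <- lapply(ops, function(g) g[g %in% genes])
  dropped <- sum(lengths(ops)) - sum(lengths(kept))
  if (dropped > 0)
    warning(dropped, " mapped gene(s) absent from the compendium; dropped",
            call. = FALSE)
  kept <- kept[lengths(kept) > 0]
  mapped <- unlist(kept, use.names = FALSE)
  singletons <- setdiff(genes, mapped)
  ops <- c(kept, stats::setNames(as.list(singletons), singletons))
  operon_map(ops)
}

#' Two-component Gaussian mixture parameters
#'
#' Equal within-state variance mixture: (1 - pi) N(mu0, sigma) +
#' pi N(mu1, sigma), with the label convention mu0 <= mu1 (inactive
#' state is the lower mean). For operon (multivariate) models, `mu0`,
#' `mu1` and `sigma` are per-gene vectors and the convention applies to
#' mean(mu1 - mu0).
#'
#' @param pi mixing proportion (probability active), in \[0, 1\].
#' @param mu0,mu1 inactive/active state means (scalar or per-gene vector).
#' @param sigma shared within-state standard deviation(s), > 0.
#' @param n_components 1 or 2.
#' @return a list with class `"mixture_model"`.
#' @export
mixture_model <- function(pi, mu0, mu1, sigma, n_components = 2L) {
  stopifnot(length(pi) == 1, pi >= 0, pi <= 1, all(sigma > 0),
            n_components %in% c(1L, 2L),
            length(mu0) == length(mu1))
  structure(list(pi = pi, mu0 = mu0, mu1 = mu1, sigma = sigma,
                 n_components = as.integer(n_components)),
            class = "mixture_model")
}

#' @export
print.mixture_model <- function(x, ...) {
  cat(sprintf("Gaussian mixture (%d component%s)\n", x$n_components,
              if (x$n_components > 1) "s" else ""))
  cat("  pi    :", format(x$pi, digits = 4), "\n")
  cat("  mu0   :", format(x$mu0, digits = 4), "\n")
  cat("  mu1   :", format(x$mu1, digits = 4), "\n")
  cat("  sigma :", format(x$sigma, digits = 4), "\n")
  invisible(x)
}

#' Prior configuration for the Gibbs samplers
#'
#' Conjugate priors: mu0 ~ N(8, var 3), mu1 ~ N(9, var 3) per gene;
#' sigma^2 ~ inverse-Wishart (univariate: scale 3, df 1; multivariate:
#' identity scale, df p + 2); pi ~ Beta(5, 5). The means 8 and 9 sit
#' near the center of typical RMA-normalized log expression.
#'
#' @param mu0_mean,mu1_mean prior means of the state means.
#' @param mu_var prior variance of the state means.
#' @param iw_scale,iw_df univariate inverse-Wishart scale and degrees of
#'   freedom for the shared variance. The multivariate sampler replaces
#'   these with identity scale and df p + 2 unless overridden there.
#' @param beta_a,beta_b Beta prior parameters for pi.
#' @return a list with class `"prior_config"`.
#' @export
prior_config <- function(mu0_mean = 8, mu1_mean = 9, mu_var = 3,
                         iw_scale = 3, iw_df = 1,
                         beta_a = 5, beta_b = 5) {
  stopifnot(mu_var > 0, iw_scale > 0, iw_df > 0, beta_a >= 1, beta_b >= 1)
  structure(list(mu0_mean = mu0_mean, mu1_mean = mu1_mean, mu_var = mu_var,
                 iw_scale = iw_scale, iw_df = iw_df,
                 beta_a = beta_a, beta_b = beta_b),
            class = "prior_config")
}

#' Gibbs sampler run configuration
#'
#' @param iterations total iterations K (default 500; fewer tends to
#'   give less robust posterior activity estimates).
#' @param burn_in burn-in b (default 50); indicators from iterations
#'   b + 1 .. K are averaged, so each a_ij is a mean of K - b binaries.
#' @param seed integer seed; per-gene/per-operon child seeds are derived
#'   from it and the unit identifier, so results are stable under
#'   compendium reordering and subsetting.
#' @return a list with class `"gibbs_config"`.
#' @export
gibbs_config <- function(iterations = 500L, burn_in = 50L, seed = NULL) {
  iterations <- as.integer(iterations); burn_in <- as.integer(burn_in)
  if (!(burn_in > 0 && burn_in < iterations))
    stop("need 0 < burn_in < iterations")
  structure(list(iterations = iterations, burn_in = burn_in, seed = seed),
            class = "gibbs_config")
}

# Deterministic 32-bit seed from a global seed and a unit identifier
# (polynomial rolling hash mod the Mersenne prime 2^31 - 1).
derive_seed <- function(seed, id) {
  h <- 0
  for (code in utf8ToInt(as.character(id)))
    h <- (h * 31 + code) %% 2147483647
  as.integer((as.numeric(seed) + h) %% 2147483647)
}

set_unit_seed <- function(cfg, id) {
  if (!is.null(cfg$seed)) set.seed(derive_seed(cfg$seed, id))
  invisible(NULL)
}

#' Read / write expression and activity matrices as TSV
#'
#' Layout: first column `gene`, remaining columns experiment ids;
#' UTF-8, decimal point. Values are written with `%.17g` so a
#' write/read round trip reproduces doubles bit-exactly.
#'
#' @param path file path.
#' @return `read_expression_tsv` returns an [expression_compendium()];
#'   `read_activity_tsv` a plain numeric matrix.
#' @export
read_expression_tsv <- function(path) {
  expression_compendium(.read_matrix_tsv(path))
}

#' @rdname read_expression_tsv
#' @export
read_activity_tsv <- function(path) .read_matrix_tsv(path)

.read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "gene") stop("first column must be 'gene'")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}

#' @rdname read_expression_tsv
#' @param x matrix with gene rownames and experiment colnames.
#' @export
write_matrix_tsv <- function(x, path) {
  x <- unclass(x)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("gene", colnames(x)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(x)), function(i)
    paste(c(rownames(x)[i], sprintf("%.17g", x[i, ])), collapse = "\t"),
    character(1))
  writeLines(body, con)
  invisible(path)
}

#' Read / write an operon map as TSV
#'
#' Columns `operon_id` and `gene`, one row per gene, grouped by operon.
#'
#' @param path file path.
#' @return an [operon_map()].
#' @export
read_operons_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("operon_id", "gene") %in% names(df)))
    stop("operon TSV needs columns 'operon_id' and 'gene'")
  operon_map(split(as.character(df$gene),
                   factor(df$operon_id, levels = unique(df$operon_id))))
}

#' @rdname read_operons_tsv
#' @param map an [operon_map()].
#' @export
write_operons_tsv <- function(map, path) {
  df <- data.frame(operon_id = rep(names(map), lengths(map)),
                   gene = unlist(map, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
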