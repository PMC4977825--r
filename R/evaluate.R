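#' Squared deviation between activity estimates and a reference
#'
#' d2_ij = (a_ij - ref_ij)^2, where the reference is either a true
#' state matrix (0/1) or a prediction matrix that may contain missing
#' cells (NA = no prediction; such cells are skipped). The
#' per-experiment summary d_j is the root of the mean d2 over genes
#' with a reference value (plots conventionally show 1 - d_j).
#'
#' @param a activity matrix (genes x experiments) in \[0, 1\].
#' @param ref reference matrix, same dimnames; NA allowed.
#' @return list with `d2` (matrix, NA where ref is missing) and
#'   `d_experiment` (named vector over experiments).
#' @export
squared_deviation <- function(a, ref) {
  stopifnot(identical(dim(a), dim(ref)))
  if (all(is.na(ref))) stop("no overlapping cells with a reference value")
  d2 <- (unclass(a) - ref)^2
  d_exp <- sqrt(colMeans(d2, na.rm = TRUE))
  list(d2 = d2, d_experiment = d_exp)
}

#' Consistency of activity estimates with a binary reference
#'
#' c_ij dichotomizes a_ij at 0.5: 1 when the call agrees with the
#' reference (a > 0.5 with ref = 1, or a < 0.5 with ref = 0), 0 when
#' it disagrees, and 0.5 when a_ij = 0.5 exactly (an unresolved call).
#' Missing reference cells yield NA and are excluded from summaries.
#'
#' @inheritParams squared_deviation
#' @return list with `c` (matrix of c_ij), `mean` (over non-missing
#'   cells), `sensitivity` (mean c over ref = 1) and `specificity`
#'   (mean c over ref = 0).
#' @export
consistency <- function(a, ref) {
  stopifnot(identical(dim(a), dim(ref)))
  vals <- ref[!is.na(ref)]
  if (!all(vals %in% c(0, 1))) stop("reference must be binary (0/1) or NA")
  a <- unclass(a)
  cc <- ifelse(a == 0.5, 0.5,
               ifelse((a > 0.5) == (ref == 1), 1, 0))
  cc[is.na(ref)] <- NA_real_
  list(c = cc,
       mean = mean(cc, na.rm = TRUE),
       sensitivity = mean(cc[ref == 1], na.rm = TRUE),
       specificity = mean(cc[ref == 0], na.rm = TRUE))
}

#' Confidence stratum of each activity estimate
#'
#' high: a < 0.2 or a > 0.8; medium: 0.2 <= a < 0.4 or 0.6 < a <= 0.8;
#' low: 0.4 <= a <= 0.6. The strata partition \[0, 1\].
#'
#' @param a numeric vector or matrix of activity estimates in \[0, 1\].
#' @return character vector/matrix of labels in
#'   \{"high", "medium", "low"\}.
#' @export
stratify_confidence <- function(a) {
  stopifnot(all(a >= 0 & a <= 1, na.rm = TRUE))
  lab <- ifelse(a < 0.2 | a > 0.8, "high",
                ifelse(a < 0.4 | a > 0.6, "medium", "low"))
  if (is.matrix(a)) dim(lab) <- dim(a)
  if (is.matrix(a)) dimnames(lab) <- dimnames(a)
  lab
}

#' Within-operon consistency classes
#'
#' For each multi-gene operon and experiment: "inconsistent" when one
#' gene has a_ij > 0.6 while another has a_ij < 0.4 (conflicting
#' confident calls); "very_consistent" when all genes are > 0.8 or all
#' < 0.2; otherwise "consistent". Inconsistent takes precedence.
#' Single-gene operons are excluded.
#'
#' @param a activity matrix.
#' @param operons an [operon_map()]; only operons with >= 2 genes
#'   present in `a` are classified.
#' @return data.frame with columns `operon`, `experiment`, `class`.
#' @export
operon_consistency <- function(a, operons) {
  a <- unclass(a)
  multi <- Filter(function(g) sum(g %in% rownames(a)) >= 2, unclass(operons))
  if (length(multi) == 0)
    return(data.frame(operon = character(0), experiment = character(0),
                      class = character(0)))
  out <- lapply(names(multi), function(op) {
    sub <- a[intersect(multi[[op]], rownames(a)), , drop = FALSE]
    cls <- vapply(seq_len(ncol(sub)), function(j) {
      v <- sub[, j]
      if (any(v > 0.6) && any(v < 0.4)) "inconsistent"
      else if (all(v > 0.8) || all(v < 0.2)) "very_consistent"
      else "consistent"
    }, character(1))
    data.frame(operon = op, experiment = colnames(sub), class = cls)
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Fraction of operon-experiment calls both consistent and correct
#'
#' Among multi-gene operon-experiment combinations, the fraction whose
#' genes are not inconsistent AND whose shared dichotomized call
#' (majority of genes at the 0.5 cut) matches the true state. Calls at
#' exactly 0.5 cannot be dichotomized and count as not-correct.
#'
#' @param a activity matrix.
#' @param operons an [operon_map()].
#' @param alpha binary truth matrix, same dimnames as `a`.
#' @return the fraction in \[0, 1\].
#' @export
correct_and_consistent <- function(a, operons, alpha) {
  a <- unclass(a)
  cls <- operon_consistency(a, operons)
  if (nrow(cls) == 0) stop("no multi-gene operons to evaluate")
  ok <- mapply(function(op, ex, cl) {
    if (cl == "inconsistent") return(FALSE)
    genes <- intersect(unclass(operons)[[op]], rownames(a))
    av <- a[genes, ex]
    tv <- alpha[genes, ex]
    # shared call: mean a dichotomized at 0.5; exactly 0.5 is unresolved
    m <- mean(av)
    if (m == 0.5) return(FALSE)
    call <- as.integer(m > 0.5)
    all(tv == call)
  }, cls$operon, cls$experiment, cls$class)
  mean(ok)
}

#' Differential activity of pathway components between experiment groups
#'
#' For each pathway component (a named gene set), the mean a_ij over
#' its genes is computed per experiment, and a two-sample Welch t-test
#' compares these per-experiment means between the two groups.
#'
#' @param a activity matrix.
#' @param components named list of gene-id vectors.
#' @param groups list of two character vectors of experiment ids (or a
#'   factor/character vector over `colnames(a)` with two levels).
#' @return data.frame with one row per component: `component`,
#'   `mean_group1`, `mean_group2`, `statistic`, `p_value`. Components
#'   with no genes in `a` are skipped with a warning.
#' @export
pathway_component_test <- function(a, components, groups) {
  a <- unclass(a)
  if (!is.list(groups)) {
    f <- factor(groups)
    stopifnot(nlevels(f) == 2, length(groups) == ncol(a))
    groups <- split(colnames(a), f)
  }
  stopifnot(length(groups) == 2, lengths(groups) > 0)
  rows <- lapply(names(components), function(cmp) {
    genes <- intersect(components[[cmp]], rownames(a))
    if (length(genes) == 0) {
      warning("component '", cmp, "' has no genes in the activity matrix",
              call. = FALSE)
      return(NULL)
    }
    per_exp <- colMeans(a[genes, , drop = FALSE])
    x <- per_exp[groups[[1]]]; y <- per_exp[groups[[2]]]
    tt <- stats::t.test(x, y)
    data.frame(component = cmp, mean_group1 = mean(x), mean_group2 = mean(y),
               statistic = unname(tt$statistic), p_value = tt$p.value)
  })
  do.call(rbind, c(Filter(Negate(is.null), rows), make.row.names = FALSE))
}

#' Association between reaction activity scores and measured fluxes
#'
#' Pearson correlation between reaction-level activity scores q and
#' square-root-transformed absolute fluxes, with a Fisher-z 95%
#' confidence interval. The square root is always applied to the
#' fluxes (they are strongly right-skewed); set `sqrt_q = TRUE` when q
#' derives from raw expression values rather than probabilities.
#'
#' @param q numeric vector of reaction activity scores.
#' @param fluxes numeric vector of measured fluxes (absolute values
#'   are taken).
#' @param sqrt_q apply the square-root transform to `q` as well.
#' @return list with `r`, `conf_int` (length 2), `p_value`, `n`.
#' @export
flux_association <- function(q, fluxes, sqrt_q = FALSE) {
  keep <- !is.na(q) & !is.na(fluxes)
  q <- q[keep]; fluxes <- fluxes[keep]
  if (length(q) < 3) stop("need at least 3 paired observations")
  y <- sqrt(abs(fluxes))
  x <- if (sqrt_q) sqrt(q) else q
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), conf_int = as.numeric(ct$conf.int),
       p_value = ct$p.value, n = length(q))
}
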