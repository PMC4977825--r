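#' Gene-reaction associations
#'
#' Each reaction is associated with genes in one of three ways:
#' `"single"` (exactly one gene), `"complex"` (a multi-gene complex:
#' all subunits required), or `"isozymes"` (any one gene suffices).
#'
#' @param assoc list of entries, each a list with `reaction`, `kind`,
#'   `genes`; or a path handled by [read_gpr_json()].
#' @return the list with class `"gpr_associations"`, validated.
#' @export
gpr_associations <- function(assoc) {
  assoc <- lapply(assoc, function(e) {
    if (!is.null(e$genes)) e$genes <- as.character(unlist(e$genes))
    e
  })
  for (e in assoc) {
    if (!all(c("reaction", "kind", "genes") %in% names(e)))
      stop("each association needs 'reaction', 'kind', 'genes'")
    if (!e$kind %in% c("single", "complex", "isozymes"))
      stop("unknown association kind: ", e$kind)
    if (e$kind == "single" && length(e$genes) != 1)
      stop("'single' association must have exactly one gene (", e$reaction, ")")
    if (e$kind != "single" && length(e$genes) < 2)
      stop("'", e$kind, "' association must have >= 2 genes (", e$reaction, ")")
  }
  if (anyDuplicated(vapply(assoc, `[[`, "", "reaction")))
    stop("duplicate reaction ids")
  structure(assoc, class = "gpr_associations")
}

#' Read gene-reaction associations from JSON
#'
#' Format: `[{"reaction": "R1", "kind": "complex",
#' "genes": ["b0001", "b0002"]}, ...]`.
#'
#' @param path path to the JSON file.
#' @return a [gpr_associations()] object.
#' @export
read_gpr_json <- function(path) {
  gpr_associations(jsonlite::fromJSON(path, simplifyDataFrame = FALSE))
}

#' Map reaction activity states to gene-level predictions
#'
#' Applies, per reaction and experiment, the rules: an active reaction
#' (r = 1) carried by a single gene or a complex marks all its genes
#' active (p = 1); an inactive reaction (r = 0) carried by a single
#' gene or isozymes marks all its genes inactive (p = 0); an active
#' isozyme reaction gives no prediction (any one isozyme could be
#' responsible), as does an inactive complex reaction (any one subunit
#' could be missing). A gene collecting both 0 and 1 across reactions
#' resolves to p = 1: a multi-role gene can be active yet perform only
#' some of its roles. Genes with no rule firing stay missing (NA).
#' The resolution is set-level (any 1 present wins), hence independent
#' of reaction order and idempotent.
#'
#' @param r binary matrix of reaction states, reactions x experiments
#'   (rownames = reaction ids).
#' @param assoc a [gpr_associations()]; every reaction in `r` must
#'   appear.
#' @return genes x experiments matrix of p_ij in \{0, 1, NA\}.
#' @export
reaction_to_gene_predictions <- function(r, assoc) {
  assoc <- gpr_associations(assoc)
  rxns <- vapply(assoc, `[[`, "", "reaction")
  missing_rxn <- setdiff(rownames(r), rxns)
  if (length(missing_rxn))
    stop("reaction(s) without association: ",
         paste(missing_rxn, collapse = ", "))
  stopifnot(all(r %in% c(0, 1)))
  genes <- unique(unlist(lapply(assoc, `[[`, "genes")))
  has1 <- matrix(FALSE, length(genes), ncol(r),
                 dimnames = list(genes, colnames(r)))
  has0 <- has1
  for (e in assoc) {
    if (!e$reaction %in% rownames(r)) next
    states <- r[e$reaction, ]
    on <- states == 1
    if (e$kind %in% c("single", "complex"))
      has1[e$genes, on] <- TRUE
    if (e$kind %in% c("single", "isozymes"))
      has0[e$genes, !on] <- TRUE
  }
  p <- matrix(NA_real_, length(genes), ncol(r),
              dimnames = list(genes, colnames(r)))
  p[has0] <- 0
  p[has1] <- 1  # contradiction rule: any active role wins
  p
}

#' Map gene activity estimates to reaction-level scores
#'
#' single: q = the gene's a; complex: q = min over the genes' a (the
#' weakest subunit limits the complex); isozymes: q = max (any one
#' isozyme suffices). Genes with no activity estimate are ignored;
#' reactions whose genes all lack estimates are dropped (absent from
#' the output rows).
#'
#' @param a activity matrix, genes x experiments (genes not covering
#'   an association are treated as missing).
#' @param assoc a [gpr_associations()].
#' @return reactions x experiments matrix of q_ij in \[0, 1\].
#' @export
gene_to_reaction_scores <- function(a, assoc) {
  assoc <- gpr_associations(assoc)
  a <- unclass(a)
  rows <- list()
  for (e in assoc) {
    genes <- intersect(e$genes, rownames(a))
    if (length(genes) == 0) next
    sub <- a[genes, , drop = FALSE]
    q <- switch(e$kind,
                single = sub[1, ],
                complex = apply(sub, 2, min),
                isozymes = apply(sub, 2, max))
    rows[[e$reaction]] <- q
  }
  if (length(rows) == 0)
    return(matrix(numeric(0), 0, ncol(a), dimnames = list(NULL, colnames(a))))
  out <- do.call(rbind, rows)
  colnames(out) <- colnames(a)
  out
}

#' Reaction states from flux variability bounds
#'
#' r_ij = 1 when the lower flux bound is strictly positive (the
#' reaction must carry flux), else 0. The bounds themselves come from
#' an upstream flux variability analysis.
#'
#' @param v_low matrix of lower flux bounds, reactions x experiments.
#' @return binary matrix of the same shape.
#' @export
reaction_states_from_bounds <- function(v_low) {
  stopifnot(is.numeric(v_low))
  (v_low > 0) * 1
}
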