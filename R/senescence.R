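#' Rank-based single-sample gene-set enrichment score for one cell
#'
#' Genes are ranked by expression in descending order (average ranks for
#' ties). Walking down the ranking, the running statistic accumulates
#' `P_in(i) - P_out(i)`, where `P_in` weights in-set genes by the alpha power
#' of their bottom-up rank `r_g = n - pos(g) + 1` and `P_out` is the fraction
#' of out-of-set genes passed so far. The score is the sum of the running
#' statistic over all positions; it is invariant to strictly increasing
#' transforms of the expression vector and its final running term is exactly
#' zero.
#'
#' @param cell_expression numeric vector of expression over genes (named, or
#'   `set` given as indices).
#' @param set character vector of gene symbols (or integer indices) in the set.
#' @param alpha rank weight exponent (0 = unweighted).
#' @return single numeric enrichment score.
#' @export
sset_score <- function(cell_expression, set, alpha = 0.25) {
  n <- length(cell_expression)
  if (is.character(set)) {
    if (is.null(names(cell_expression))) stop("named expression vector required for symbol sets")
    idx <- match(set, names(cell_expression))
    idx <- idx[!is.na(idx)]
  } else idx <- set
  m <- length(idx)
  if (m == 0 || m >= n) stop("set must be non-empty and smaller than the gene universe")
  r <- rank(cell_expression, ties.method = "average")  # bottom-up rank = n - pos + 1
  inset <- logical(n); inset[idx] <- TRUE
  w <- r[inset]^alpha
  sum(w * r[inset]) / sum(w) - sum(r[!inset]) / (n - m)
}

#' Score every cell against every gene set
#'
#' Applies [sset_score()] per cell per set after removing the exclusion-list
#' symbols and intersecting with measured genes. Uses the normalized matrix.
#'
#' @param expr normalized [ExpressionMatrix()].
#' @param sets [GeneSetCollection()].
#' @param alpha rank weight exponent.
#' @return list of class `ScoreTable`: `scores` (cells x sets matrix),
#'   `set_sizes` (effective sizes after exclusion/intersection), `alpha`.
#' @export
score_all <- function(expr, sets, alpha = 0.25) {
  nm <- get_norm(expr)
  genes <- rownames(nm)
  n <- length(genes)
  eff <- lapply(sets$sets, function(s) {
    s <- setdiff(s, sets$exclusion)
    intersect(s, genes)
  })
  bad <- names(eff)[vapply(eff, length, integer(1)) == 0]
  if (length(bad))
    stop("gene set(s) empty after exclusion/intersection: ", paste(bad, collapse = ", "))
  R <- col_ranks(nm)                       # genes x cells ascending ranks
  scores <- vapply(names(eff), function(nmset) {
    idx <- match(eff[[nmset]], genes)
    m <- length(idx)
    if (m >= n) stop("set covers the whole gene universe: ", nmset)
    ri <- R[idx, , drop = FALSE]
    w <- ri^alpha
    p_in <- colSums(w * ri) / colSums(w)
    p_out <- (colSums(R) - colSums(ri)) / (n - m)
    p_in - p_out
  }, numeric(ncol(nm)))
  rownames(scores) <- colnames(nm)
  structure(list(scores = scores,
                 set_sizes = vapply(eff, length, integer(1)),
                 alpha = alpha),
            class = "ScoreTable")
}

#' Unified senescence classification by per-type median split
#'
#' Within each cell type (age groups pooled), each score column is split at
#' its median; a cell's per-set indicator is TRUE when its score is strictly
#' above the median (ties at the median fall in the lower half). The
#' senescent flag combines the per-set indicators: all sets (default), any
#' set, or at least `k` of them.
#'
#' @param scores a `ScoreTable` from [score_all()] (or a cells x sets matrix).
#' @param cell_types character vector of cell-type labels, one per cell.
#' @param rule `"all"`, `"any"`, or `"k_of_4"` with `k` given by `k`.
#' @param k number of sets required when `rule = "k_of_4"`.
#' @param required_sets columns that must be present (default: the four
#'   senescence sets used for the unified call, when available; otherwise all
#'   columns are used).
#' @return list of class `SenescenceCall`: `senescent` (named logical),
#'   `indicators` (cells x sets logical), `cell_type`, `rule`.
#' @export
uss_classify <- function(scores, cell_types, rule = c("all", "any", "k_of_4"),
                         k = 3, required_sets = NULL) {
  rule <- match.arg(rule)
  S <- if (inherits(scores, "ScoreTable")) scores$scores else as.matrix(scores)
  uss_sets <- c("SenMayo", "CellAge", "GenAge", "SenescenceEigengene")
  if (is.null(required_sets))
    required_sets <- if (all(uss_sets %in% colnames(S))) uss_sets else colnames(S)
  missing <- setdiff(required_sets, colnames(S))
  if (length(missing)) stop("missing score column(s): ", paste(missing, collapse = ", "))
  S <- S[, required_sets, drop = FALSE]
  stopifnot(length(cell_types) == nrow(S))
  ind <- matrix(FALSE, nrow(S), ncol(S), dimnames = dimnames(S))
  for (ct in unique(cell_types)) {
    sel <- cell_types == ct
    if (sum(sel) < 2) {         # a median split needs at least two cells
      warning("cell type ", ct, " has fewer than 2 cells; skipped")
      next
    }
    med <- apply(S[sel, , drop = FALSE], 2, stats::median)
    ind[sel, ] <- sweep(S[sel, , drop = FALSE], 2, med, ">")
  }
  flag <- switch(rule,
                 all = rowSums(ind) == ncol(ind),
                 any = rowSums(ind) > 0,
                 k_of_4 = rowSums(ind) >= k)
  names(flag) <- rownames(S)
  structure(list(senescent = flag, indicators = ind,
                 cell_type = cell_types, rule = rule),
            class = "SenescenceCall")
}

#' Senescent-cell percentages per cell type and age group
#'
#' @param call [uss_classify()] result.
#' @param metadata per-cell data.frame with `cell_id`, `cell_type`, `age_group`.
#' @return data.frame of (cell_type, age_group, n_cells, n_senescent,
#'   pct_senescent).
#' @export
sn_fraction_table <- function(call, metadata) {
  m <- match(names(call$senescent), metadata$cell_id)
  if (anyNA(m)) stop("metadata missing cells present in the call")
  df <- data.frame(cell_type = metadata$cell_type[m],
                   age_group = metadata$age_group[m],
                   sn = unname(call$senescent))
  agg <- stats::aggregate(sn ~ cell_type + age_group, df,
                          function(x) c(n = length(x), k = sum(x)))
  out <- data.frame(cell_type = agg$cell_type, age_group = agg$age_group,
                    n_cells = agg$sn[, "n"], n_senescent = agg$sn[, "k"])
  out$pct_senescent <- 100 * out$n_senescent / out$n_cells
  out[order(out$cell_type, out$age_group), ]
}
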