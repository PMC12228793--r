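#' Tukey trimean expression aggregate per cell type
#'
#' (Q1 + 2*Q2 + Q3) / 4 of normalized expression per gene per cell type,
#' with linear-interpolation quartiles. A robust location estimate for the
#' type-level ligand/receptor abundance entering the communication model.
#'
#' @param expr normalized [ExpressionMatrix()].
#' @param cell_types labels per cell (default from metadata).
#' @param genes optional subset of genes to aggregate.
#' @return genes x types numeric matrix.
#' @export
trimean_by_type <- function(expr, cell_types = NULL, genes = NULL) {
  nm <- get_norm(expr)
  if (is.null(cell_types)) cell_types <- expr$cells$cell_type
  stopifnot(length(cell_types) == ncol(nm))
  if (!is.null(genes)) nm <- nm[intersect(genes, rownames(nm)), , drop = FALSE]
  types <- sort(unique(cell_types))
  small <- types[vapply(types, function(t) sum(cell_types == t) < 3, logical(1))]
  if (length(small)) stop("cell type(s) with < 3 cells: ", paste(small, collapse = ", "))
  out <- vapply(types, function(t) {
    sub <- nm[, cell_types == t, drop = FALSE]
    q <- t(apply(sub, 1, stats::quantile, probs = c(0.25, 0.5, 0.75),
                 type = 5, names = FALSE))
    (q[, 1] + 2 * q[, 2] + q[, 3]) / 4
  }, numeric(nrow(nm)))
  rownames(out) <- rownames(nm)
  out
}

#' Hill-form ligand-receptor communication probability
#'
#' P = L*R / (Kh + L*R): a saturating mass-action probability, strictly
#' increasing in each aggregate, in \[0, 1). Multi-subunit ligands or
#' receptors are collapsed by the geometric mean of their subunit aggregates
#' before entering the product.
#'
#' @param L_agg,R_agg non-negative ligand / receptor aggregates (scalars or
#'   vectors of subunit values to collapse).
#' @param Kh half-saturation constant.
#' @return probability in \[0, 1).
#' @export
lr_probability <- function(L_agg, R_agg, Kh = 0.5) {
  if (any(L_agg < 0) || any(R_agg < 0)) stop("aggregates must be non-negative")
  L <- if (length(L_agg) > 1) exp(mean(log(pmax(L_agg, 0)))) else L_agg
  R <- if (length(R_agg) > 1) exp(mean(log(pmax(R_agg, 0)))) else R_agg
  x <- L * R
  x / (Kh + x)
}

#' Communication probabilities with permutation significance
#'
#' For every (sender type, receiver type, LR pair) triple, computes the
#' Hill-form probability from trimean aggregates and a permutation p-value:
#' cell-type labels are permuted jointly across cells `n_perm` times and
#' p = (1 + #permuted P >= observed P) / (n_perm + 1). An observed
#' probability of 0 gets p = 1 by construction.
#'
#' @param expr normalized [ExpressionMatrix()].
#' @param lr LR table ([read_lr_table()] / [generate_lr_table()]).
#' @param cell_types labels per cell (default from metadata).
#' @param n_perm number of permutations (>= 20).
#' @param Kh half-saturation constant of [lr_probability()].
#' @param seed permutation seed.
#' @param group optional group label stored with the tensor.
#' @return long data.frame of class `CommunicationTensor`: sender, receiver,
#'   pair_id, pathway, prob, p.
#' @export
permutation_significance <- function(expr, lr, cell_types = NULL, n_perm = 100,
                                     Kh = 0.5, seed = 1, group = NA_character_) {
  if (n_perm < 20) stop("n_perm must be >= 20")
  nm <- get_norm(expr)
  if (is.null(cell_types)) cell_types <- expr$cells$cell_type
  genes <- unique(unlist(c(lr$ligand, lr$receptor)))
  genes <- intersect(genes, rownames(nm))
  sub <- nm[genes, , drop = FALSE]
  types <- sort(unique(cell_types))

  tensor_probs <- function(labels) {
    agg <- trimean_rows(sub, labels, types)
    probs_from_agg(agg, lr, types, Kh)
  }
  obs <- tensor_probs(cell_types)
  exceed <- matrix(0L, nrow(obs), 1)
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      pp <- tensor_probs(sample(cell_types))
      exceed <- exceed + (pp$prob >= obs$prob)
    }
  })
  obs$p <- (1 + as.numeric(exceed)) / (n_perm + 1)
  obs$p[obs$prob == 0] <- 1
  obs$group <- group
  class(obs) <- c("CommunicationTensor", "data.frame")
  obs
}

# trimean per row for given labels over a fixed type universe
trimean_rows <- function(sub, labels, types) {
  vapply(types, function(t) {
    m <- sub[, labels == t, drop = FALSE]
    q <- t(apply(m, 1, stats::quantile, probs = c(0.25, 0.5, 0.75),
                 type = 5, names = FALSE))
    (q[, 1] + 2 * q[, 2] + q[, 3]) / 4
  }, numeric(nrow(sub)))
}

# expand aggregates into the long sender x receiver x pair probability table
probs_from_agg <- function(agg, lr, types, Kh) {
  grid <- expand.grid(sender = types, receiver = types,
                      pair = seq_len(nrow(lr)), stringsAsFactors = FALSE)
  lagg <- function(subunits, type) {
    v <- agg[intersect(subunits, rownames(agg)), type]
    if (!length(v)) 0 else if (length(v) > 1) exp(mean(log(pmax(v, 0)))) else v
  }
  prob <- mapply(function(s, r, k) {
    L <- lagg(lr$ligand[[k]], s)
    R <- lagg(lr$receptor[[k]], r)
    lr_probability(L, R, Kh)
  }, grid$sender, grid$receiver, grid$pair)
  data.frame(sender = grid$sender, receiver = grid$receiver,
             pair_id = lr$pair_id[grid$pair], pathway = lr$pathway[grid$pair],
             prob = as.numeric(prob), stringsAsFactors = FALSE)
}

#' Interaction strength, information flow and group differences
#'
#' Keeps significant entries (p < `p_cut`), then aggregates: total strength
#' (sum of probabilities), sender x receiver strength matrix, per-pathway
#' information flow (sum over the pathway's pairs and all type pairs). With
#' two tensors, also returns the A - B difference matrix and relative flows
#' (flow_group / sum over groups).
#'
#' @param tensor [permutation_significance()] result.
#' @param tensor_b optional second tensor over the same LR universe.
#' @param p_cut significance threshold applied before aggregation.
#' @return list: `total`, `matrix`, `flow` and, with `tensor_b`, `total_b`,
#'   `matrix_b`, `flow_b`, `diff_matrix`, `relative_flow`.
#' @export
interaction_strength <- function(tensor, tensor_b = NULL, p_cut = 0.05) {
  agg_one <- function(tn) {
    sig <- tn[tn$p < p_cut, , drop = FALSE]
    types <- sort(unique(c(tn$sender, tn$receiver)))
    m <- matrix(0, length(types), length(types), dimnames = list(types, types))
    if (nrow(sig)) {
      s <- stats::aggregate(prob ~ sender + receiver, sig, sum)
      m[cbind(s$sender, s$receiver)] <- s$prob
    }
    fl <- stats::setNames(rep(0, length(unique(tn$pathway))), sort(unique(tn$pathway)))
    if (nrow(sig)) {
      f <- stats::aggregate(prob ~ pathway, sig, sum)
      fl[f$pathway] <- f$prob
    }
    list(total = sum(sig$prob), matrix = m, flow = fl)
  }
  a <- agg_one(tensor)
  if (is.null(tensor_b))
    return(list(total = a$total, matrix = a$matrix, flow = a$flow))
  if (!setequal(tensor$pair_id, tensor_b$pair_id))
    stop("tensors do not share the same LR pair universe")
  b <- agg_one(tensor_b)
  paths <- sort(unique(c(names(a$flow), names(b$flow))))
  fa <- stats::setNames(rep(0, length(paths)), paths); fa[names(a$flow)] <- a$flow
  fb <- stats::setNames(rep(0, length(paths)), paths); fb[names(b$flow)] <- b$flow
  tot <- fa + fb
  rel <- cbind(a = ifelse(tot > 0, fa / tot, NA), b = ifelse(tot > 0, fb / tot, NA))
  list(total = a$total, matrix = a$matrix, flow = fa,
       total_b = b$total, matrix_b = b$matrix, flow_b = fb,
       diff_matrix = a$matrix - b$matrix, relative_flow = rel)
}
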