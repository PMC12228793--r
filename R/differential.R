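#' Rank-sum differential expression between two cell groups
#'
#' Per-gene two-sided Wilcoxon rank-sum test on normalized expression with a
#' tie-corrected normal approximation (continuity-corrected); when both
#' groups have at most `exact_max` cells and a gene has no ties, the exact
#' null enumeration is used instead. log2 fold change uses a pseudocount on
#' the normalized scale. P-values are Benjamini-Hochberg adjusted across the
#' tested genes.
#'
#' @param expr normalized [ExpressionMatrix()], or a plain genes x cells
#'   numeric matrix of normalized values.
#' @param labels logical or two-level vector over cells; TRUE / first level =
#'   group A.
#' @param pc pseudocount added to group means before the log2 ratio.
#' @param exact_max maximum per-group size for the exact branch.
#' @param delog_fc compute the fold change on the de-logged scale
#'   (`expm1` of the log-normalized values, i.e. counts-per-scale), the
#'   convention under which a 2-fold expression shift gives log2FC of about 1.
#'   Defaults to TRUE for [ExpressionMatrix()] input, FALSE for a plain
#'   matrix. The test itself is rank-based and unaffected.
#' @return data.frame of class `DeResult`: gene, mean_a, mean_b, log2fc,
#'   statistic (rank-sum W of group A), p, q.
#' @export
rank_sum_de <- function(expr, labels, pc = 0.01, exact_max = 10,
                        delog_fc = inherits(expr, "ExpressionMatrix")) {
  nm <- if (inherits(expr, "ExpressionMatrix")) get_norm(expr) else as.matrix(expr)
  if (is.logical(labels)) {
    ga <- labels
  } else {
    lv <- unique(as.character(labels))
    if (length(lv) != 2) stop("labels must have exactly two levels")
    ga <- as.character(labels) == lv[1]
  }
  na <- sum(ga); nb <- sum(!ga)
  if (na < 3 || nb < 3) stop("need >= 3 cells per group")
  A <- nm[, ga, drop = FALSE]; B <- nm[, !ga, drop = FALSE]
  if (delog_fc) {
    mean_a <- rowMeans(expm1(A)); mean_b <- rowMeans(expm1(B))
  } else {
    mean_a <- rowMeans(A); mean_b <- rowMeans(B)
  }

  R <- t(apply(nm, 1, rank, ties.method = "average"))
  W <- rowSums(R[, ga, drop = FALSE]) - na * (na + 1) / 2   # Mann-Whitney U of A

  # tie-corrected normal approximation with continuity correction
  n <- na + nb
  tie_term <- apply(nm, 1, function(x) {
    tt <- table(x)
    sum(tt^3 - tt)
  })
  sigma2 <- na * nb / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  z <- W - na * nb / 2
  p <- ifelse(sigma2 <= 0, 1,
              2 * stats::pnorm((abs(z) - 0.5) / sqrt(pmax(sigma2, 1e-300)),
                               lower.tail = FALSE))
  p <- pmin(p, 1)

  if (na <= exact_max && nb <= exact_max) {
    no_ties <- tie_term == 0
    if (any(no_ties)) {
      Wnt <- W[no_ties]
      p[no_ties] <- vapply(Wnt, function(w) {
        lo <- stats::pwilcox(w, na, nb)
        hi <- stats::pwilcox(w - 1, na, nb, lower.tail = FALSE)
        min(1, 2 * min(lo, hi))
      }, numeric(1))
    }
  }
  ra <- mean_a + pc; rb <- mean_b + pc
  l2 <- rep(NA_real_, length(ra))
  ok <- ra > 0 & rb > 0
  l2[ok] <- log2(ra[ok] / rb[ok])
  l2[mean_a == mean_b] <- 0
  out <- data.frame(gene = rownames(nm), mean_a = mean_a, mean_b = mean_b,
                    log2fc = l2,
                    statistic = W, p = p,
                    q = stats::p.adjust(p, method = "BH"),
                    row.names = NULL)
  class(out) <- c("DeResult", "data.frame")
  out
}

#' Catalogue differential genes across cell types
#'
#' Applies the up/down thresholds per cell type and summarizes cross-type
#' sharing: the union of up- (and down-) regulated genes, per-type lists, and
#' the counts of genes shared in exactly / at least k types.
#'
#' @param de_list named list of [rank_sum_de()] results, one per cell type
#'   (group A = senescent).
#' @param lfc_cut absolute log2 fold-change threshold (up: > lfc_cut, down:
#'   < -lfc_cut).
#' @param q_cut adjusted p-value threshold.
#' @return list: `up`, `down` (per-type gene lists), `up_union`,
#'   `down_union`, `sharing` (data.frame gene x direction with n_types),
#'   `shared_at_least` (direction x k counts).
#' @export
sn_deg_catalog <- function(de_list, lfc_cut = 0.5, q_cut = 0.05) {
  if (length(de_list) < 2) stop("need DeResults for >= 2 cell types")
  pick <- function(de, dir) {
    sig <- de$q < q_cut & (if (dir == "up") de$log2fc > lfc_cut else de$log2fc < -lfc_cut)
    de$gene[sig & !is.na(sig)]
  }
  up <- lapply(de_list, pick, dir = "up")
  down <- lapply(de_list, pick, dir = "down")
  sharing <- function(lists) {
    u <- sort(unique(unlist(lists)))
    if (!length(u)) return(data.frame(gene = character(0), n_types = integer(0)))
    counts <- rowSums(vapply(lists, function(l) u %in% l, logical(length(u))))
    data.frame(gene = u, n_types = as.integer(counts))
  }
  su <- sharing(up); sd_ <- sharing(down)
  kmax <- length(de_list)
  shared_at_least <- data.frame(
    k = seq_len(kmax),
    up = vapply(seq_len(kmax), function(k) sum(su$n_types >= k), integer(1)),
    down = vapply(seq_len(kmax), function(k) sum(sd_$n_types >= k), integer(1)))
  list(up = up, down = down,
       up_union = su$gene, down_union = sd_$gene,
       sharing_up = su, sharing_down = sd_,
       shared_at_least = shared_at_least)
}

#' Intersect an up-regulated DEG catalogue with the SASP set
#'
#' Per-type up-regulated SASP genes, a gene x cell-type membership matrix and
#' the combination counts (shared in exactly k / at least k types, unique).
#'
#' @param catalog [sn_deg_catalog()] result.
#' @param sasp_set character vector of SASP gene symbols.
#' @return list of class `SaspCatalog`: `per_type`, `membership`,
#'   `union_size`, `shared_exactly`, `shared_at_least`.
#' @export
intersect_sasp <- function(catalog, sasp_set) {
  if (!length(sasp_set)) stop("SASP set is empty")
  per_type <- lapply(catalog$up, intersect, y = sasp_set)
  u <- sort(unique(unlist(per_type)))
  memb <- vapply(per_type, function(l) u %in% l, logical(length(u)))
  if (length(u) == 0) memb <- matrix(FALSE, 0, length(per_type),
                                     dimnames = list(NULL, names(per_type)))
  n_types <- if (length(u)) rowSums(memb) else integer(0)
  kmax <- length(per_type)
  structure(list(
    per_type = per_type,
    membership = if (length(u)) `rownames<-`(memb, u) else memb,
    union_size = length(u),
    shared_exactly = vapply(seq_len(kmax), function(k) sum(n_types == k), integer(1)),
    shared_at_least = vapply(seq_len(kmax), function(k) sum(n_types >= k), integer(1))),
    class = "SaspCatalog")
}

#' One-sided hypergeometric over-representation
#'
#' For each annotation set, tests whether the query contains more of the
#' set's genes than expected from the universe: p = P\[X >= k\] with
#' (N, K, n, k) = (|universe|, |set in universe|, |query|, |set in query|).
#' BH adjustment across sets.
#'
#' @param query character gene set (must be a subset of `universe`).
#' @param universe character background set.
#' @param annotation named list of character gene sets.
#' @return data.frame: set, N, K, n, k, fold_enrichment, p, q.
#' @export
hypergeom_enrich <- function(query, universe, annotation) {
  query <- unique(query); universe <- unique(universe)
  if (!all(query %in% universe)) stop("query must be a subset of the universe")
  N <- length(universe); n <- length(query)
  rows <- lapply(names(annotation), function(nm) {
    K <- length(intersect(annotation[[nm]], universe))
    k <- length(intersect(annotation[[nm]], query))
    p <- if (K == 0) 1 else stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    fe <- if (K == 0 || n == 0) NA_real_ else (k / n) / (K / N)
    data.frame(set = nm, N = N, K = K, n = n, k = k, fold_enrichment = fe, p = p)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}
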