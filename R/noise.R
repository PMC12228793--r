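#' Select invariant genes by coefficient of variation
#'
#' Among genes detected (count > 0) in at least half the cells, ranks genes
#' by the coefficient of variation of their normalized expression and returns
#' the lowest-CV fraction. Deterministic; a user-supplied list can be used in
#' its place downstream.
#'
#' @param expr normalized [ExpressionMatrix()].
#' @param fraction fraction of eligible genes to return (0, 1].
#' @param min_eligible minimum number of eligible genes required.
#' @return character vector of gene symbols.
#' @export
select_invariant_genes <- function(expr, fraction = 0.10, min_eligible = 100) {
  stopifnot(fraction > 0, fraction <= 1)
  nm <- get_norm(expr)
  det <- Matrix::rowSums(expr$counts > 0) / ncol(expr$counts)
  elig <- which(det >= 0.5)
  if (length(elig) < min_eligible)
    stop("too few genes detected in >= 50% of cells (", length(elig), ")")
  mu <- rowMeans(nm[elig, , drop = FALSE])
  sd_ <- apply(nm[elig, , drop = FALSE], 1, stats::sd)
  cv <- sd_ / mu
  k <- max(1L, floor(fraction * length(elig)))
  keep <- elig[order(cv, rownames(nm)[elig])[seq_len(k)]]
  rownames(nm)[sort(keep)]
}

#' Depth- and composition-controlled transcriptional noise
#'
#' The statistic is the Euclidean distance of each cell to its own
#' (cell type, age group) centroid in invariant-gene space, computed after
#' controlling sequencing depth and group composition: cells below the target
#' depth are dropped, the rest are downsampled to exactly `depth` UMIs, the
#' larger age group of each cell type is randomly subsampled to the smaller
#' one's size, and expression is log-normalized on the invariant genes.
#' Distances are averaged per donor; the aged/young ratio of donor means and
#' two-sided rank-sum tests at the cell and donor level are reported per
#' cell type.
#'
#' @param expr [ExpressionMatrix()] with raw counts and `age_group`,
#'   `cell_type`, `donor` metadata.
#' @param invariant_genes character vector (e.g. [select_invariant_genes()]).
#' @param depth target UMI depth.
#' @param seed seed for downsampling and group equalization.
#' @param min_cells minimum cells per age group per type; smaller types are
#'   skipped with a warning.
#' @return list of class `NoiseResult`: `per_cell` (cell, type, group, donor,
#'   distance), `per_donor`, `per_type` (ratio of donor-mean distances and
#'   rank-sum p-values), `params`.
#' @export
transcriptional_noise <- function(expr, invariant_genes, depth, seed = 1,
                                  min_cells = 10) {
  tot <- Matrix::colSums(expr$counts)
  keep <- tot >= depth
  if (!any(keep)) stop("no cells at or above the target depth")
  expr <- subset_cells(expr, colnames(expr$counts)[keep])
  expr <- downsample_umis(expr, depth, seed = seed)

  meta <- expr$cells
  per_cell <- NULL
  with_seed(seed + 1L, {
    for (ct in unique(meta$cell_type)) {
      sel <- which(meta$cell_type == ct)
      ny <- sum(meta$age_group[sel] == "young")
      na <- sum(meta$age_group[sel] == "aged")
      if (min(ny, na) < min_cells) {
        warning("cell type ", ct, " has < ", min_cells, " cells in a group; skipped")
        next
      }
      m <- min(ny, na)
      ys <- sample(sel[meta$age_group[sel] == "young"], m)
      as_ <- sample(sel[meta$age_group[sel] == "aged"], m)
      use <- c(ys, as_)
      sub <- subset_cells(expr, meta$cell_id[use])
      sub <- normalize_log(sub)
      nmat <- sub$norm[intersect(invariant_genes, rownames(sub$norm)), , drop = FALSE]
      for (gr in c("young", "aged")) {
        gi <- sub$cells$age_group == gr
        centroid <- rowMeans(nmat[, gi, drop = FALSE])
        d <- sqrt(colSums((nmat[, gi, drop = FALSE] - centroid)^2))
        per_cell <- rbind(per_cell, data.frame(
          cell_id = sub$cells$cell_id[gi], cell_type = ct, age_group = gr,
          donor = sub$cells$donor[gi], distance = unname(d)))
      }
    }
  })
  if (is.null(per_cell)) stop("no cell type passed the group-size requirement")

  per_donor <- stats::aggregate(distance ~ donor + age_group + cell_type,
                                per_cell, mean)
  per_type <- do.call(rbind, lapply(split(per_cell, per_cell$cell_type), function(pc) {
    dn <- stats::aggregate(distance ~ donor + age_group, pc, mean)
    ya <- dn$distance[dn$age_group == "young"]
    aa <- dn$distance[dn$age_group == "aged"]
    cy <- pc$distance[pc$age_group == "young"]
    ca <- pc$distance[pc$age_group == "aged"]
    ratio <- if (mean(ya) > 0) mean(aa) / mean(ya) else NA_real_
    if (stats::sd(pc$distance) == 0) {
      warning("all distances identical in ", pc$cell_type[1], "; ratio reported as NA")
      ratio <- NA_real_
    }
    data.frame(cell_type = pc$cell_type[1],
               ratio_aged_young = ratio,
               p_cell = tryCatch(suppressWarnings(stats::wilcox.test(ca, cy)$p.value),
                                 error = function(e) NA_real_),
               p_donor = if (length(ya) >= 2 && length(aa) >= 2)
                 tryCatch(suppressWarnings(stats::wilcox.test(aa, ya)$p.value),
                          error = function(e) NA_real_)
               else NA_real_)
  }))
  rownames(per_type) <- NULL
  structure(list(per_cell = per_cell, per_donor = per_donor, per_type = per_type,
                 params = list(depth = depth, seed = seed,
                               invariant_genes = invariant_genes)),
            class = "NoiseResult")
}
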