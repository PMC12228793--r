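#' Quality-control thresholds
#'
#' Strict-inequality bounds on per-cell totals: cells are kept when
#' UMI > `rna_umi_min`, UMI < `rna_umi_max`, mitochondrial percent <
#' `mito_pct_max` and, when ATAC data is present, total fragments >
#' `atac_min` and < `atac_max`.
#'
#' @param rna_umi_min,rna_umi_max bounds on total UMI per cell.
#' @param mito_pct_max upper bound on mitochondrial UMI percentage.
#' @param atac_min,atac_max bounds on total ATAC fragment counts per cell.
#' @return list of class `QcThresholds`.
#' @export
qc_thresholds <- function(rna_umi_min = 1000, rna_umi_max = 40000,
                          mito_pct_max = 20, atac_min = 1000, atac_max = 100000) {
  stopifnot(rna_umi_min < rna_umi_max, atac_min < atac_max, mito_pct_max > 0)
  structure(list(rna_umi_min = rna_umi_min, rna_umi_max = rna_umi_max,
                 mito_pct_max = mito_pct_max, atac_min = atac_min,
                 atac_max = atac_max), class = "QcThresholds")
}

#' Filter cells on RNA and ATAC quality rules
#'
#' Applies the strict-inequality rules of [qc_thresholds()] as a conjunction.
#' Mitochondrial percentage is computed on raw counts. A cell sitting exactly
#' on a bound is excluded.
#'
#' @param rna [ExpressionMatrix()].
#' @param atac optional [AccessibilityMatrix()] sharing cell ids with `rna`.
#' @param th [qc_thresholds()].
#' @return list with `rna`, `atac` (filtered, or NULL) and `report`, a
#'   data.frame of per-rule exclusion counts plus cells retained.
#' @export
qc_filter <- function(rna, atac = NULL, th = qc_thresholds()) {
  umi <- Matrix::colSums(rna$counts)
  mito_pct <- 100 * Matrix::colSums(rna$counts[rna$mito, , drop = FALSE]) / pmax(umi, 1)
  fail_low <- !(umi > th$rna_umi_min)
  fail_high <- !(umi < th$rna_umi_max)
  fail_mito <- !(mito_pct < th$mito_pct_max)
  keep <- !(fail_low | fail_high | fail_mito)
  fail_atac_low <- fail_atac_high <- rep(FALSE, length(umi))
  if (!is.null(atac)) {
    if (!identical(colnames(atac$counts), colnames(rna$counts)))
      stop("rna and atac must share cell ids in order")
    at <- Matrix::colSums(atac$counts)
    fail_atac_low <- !(at > th$atac_min)
    fail_atac_high <- !(at < th$atac_max)
    keep <- keep & !(fail_atac_low | fail_atac_high)
  }
  if (!any(keep)) warning("no cells pass QC")
  report <- data.frame(
    rule = c("rna_umi_low", "rna_umi_high", "mito_pct_high",
             "atac_low", "atac_high", "retained"),
    n = c(sum(fail_low), sum(fail_high), sum(fail_mito),
          sum(fail_atac_low), sum(fail_atac_high), sum(keep)))
  ids <- colnames(rna$counts)[keep]
  out_rna <- if (any(keep)) subset_cells(rna, ids) else NULL
  out_atac <- NULL
  if (!is.null(atac) && any(keep)) {
    sel <- match(ids, colnames(atac$counts))
    out_atac <- AccessibilityMatrix(atac$counts[, sel, drop = FALSE], atac$peaks,
                                    atac$cells[sel, , drop = FALSE])
  }
  list(rna = out_rna, atac = out_atac, report = report)
}

#' Log-normalize counts to a fixed scale per cell
#'
#' value = ln(1 + scale * count / cell_total) (CP10k by default). The
#' transform is monotone within each cell and invariant to uniform scaling of
#' a cell's counts, which is what the downstream rank- and median-split-based
#' statistics require.
#'
#' @param mat [ExpressionMatrix()] (no zero-total cells).
#' @param scale per-cell target total before `log1p`.
#' @return the input with a `norm` element (dense genes x cells matrix).
#' @export
normalize_log <- function(mat, scale = 1e4) {
  tot <- Matrix::colSums(mat$counts)
  if (any(tot == 0)) stop("zero-total cell; run qc_filter first")
  nm <- as.matrix(mat$counts %*% Matrix::Diagonal(x = scale / tot))
  dimnames(nm) <- dimnames(mat$counts)
  mat$norm <- log1p(nm)
  mat
}

#' Downsample each cell to a fixed number of UMIs
#'
#' True molecule subsampling: for cells with total > `depth`, exactly `depth`
#' molecules are drawn without replacement from the cell's molecule pool
#' (multivariate hypergeometric). Cells already at or below `depth` are left
#' unchanged.
#'
#' @param mat [ExpressionMatrix()].
#' @param depth target UMI total (> 0).
#' @param seed integer seed; output is deterministic given (depth, seed).
#' @return [ExpressionMatrix()] with downsampled counts.
#' @export
downsample_umis <- function(mat, depth, seed = 1) {
  stopifnot(depth > 0)
  X <- as(mat$counts, "CsparseMatrix")
  tot <- Matrix::colSums(X)
  xv <- X@x
  with_seed(seed, {
    for (cellj in which(tot > depth)) {
      ptr <- (X@p[cellj] + 1):X@p[cellj + 1]
      k <- xv[ptr]
      drawn <- numeric(length(k))
      remaining <- depth
      tot_rem <- sum(k)
      for (i in seq_along(k)) {         # sequential multivariate hypergeometric
        if (remaining == 0) break
        x <- stats::rhyper(1, k[i], tot_rem - k[i], remaining)
        drawn[i] <- x
        remaining <- remaining - x
        tot_rem <- tot_rem - k[i]
      }
      xv[ptr] <- drawn
    }
  })
  X@x <- xv
  X <- Matrix::drop0(X)
  ExpressionMatrix(X, mat$cells, mat$mito)
}
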