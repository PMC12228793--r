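#' Principal-axis pseudotime over a set of ordering genes
#'
#' Projects cells on the first principal axis of the normalized
#' ordering-gene submatrix, rank-transforms the projection to \[0, 1\], and
#' orients the axis so that the anchor group (aged cells by default) has the
#' larger mean pseudotime. The orientation rule makes the output invariant to
#' the arbitrary sign of the principal axis. A user-supplied pseudotime (TSV
#' with cell_id and pseudotime) can be used anywhere this output is consumed.
#'
#' @param expr normalized [ExpressionMatrix()] with `age_group` metadata.
#' @param ordering_genes character vector (>= 2 present in the matrix).
#' @param anchor orientation rule; `"aged_late"` orients aged-cell mean late.
#' @return data.frame of class `TrajectoryFrame`: cell_id, pseudotime;
#'   attributes `ordering_genes`, `anchor`.
#' @export
fit_pseudotime <- function(expr, ordering_genes, anchor = "aged_late") {
  nm <- get_norm(expr)
  og <- intersect(ordering_genes, rownames(nm))
  if (length(og) < 2) stop("need >= 2 ordering genes present in the matrix")
  X <- t(nm[og, , drop = FALSE])
  if (all(apply(X, 2, stats::sd) == 0)) stop("zero-variance ordering-gene submatrix")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = 1)
  proj <- pc$x[, 1]
  n <- length(proj)
  pt <- (rank(proj, ties.method = "average") - 1) / max(n - 1, 1)
  if (anchor == "aged_late" && "age_group" %in% names(expr$cells)) {
    aged <- expr$cells$age_group == "aged"
    if (any(aged) && any(!aged) && mean(pt[aged]) < mean(pt[!aged])) pt <- 1 - pt
  }
  out <- data.frame(cell_id = colnames(nm), pseudotime = unname(pt))
  attr(out, "ordering_genes") <- og
  attr(out, "anchor") <- anchor
  class(out) <- c("TrajectoryFrame", "data.frame")
  out
}

#' Spearman correlation of every gene with pseudotime
#'
#' Tie-aware Spearman rho per gene, p-value via the t approximation, BH
#' adjustment across genes. Constant genes get NA rho.
#'
#' @param expr normalized [ExpressionMatrix()].
#' @param pt numeric pseudotime per cell (same order as columns) or a
#'   [fit_pseudotime()] frame.
#' @return data.frame: gene, rho, p, q.
#' @export
pt_gene_correlation <- function(expr, pt) {
  nm <- get_norm(expr)
  if (inherits(pt, "data.frame")) pt <- pt$pseudotime[match(colnames(nm), pt$cell_id)]
  n <- ncol(nm)
  if (n < 10) stop("need >= 10 cells")
  z <- row_rank_z(nm)
  rho <- spearman_rows(z, pt)
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, 1e-12))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[is.na(rho)] <- NA
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  data.frame(gene = rownames(nm), rho = rho, p = p, q = q, row.names = NULL)
}

#' Sliding-window module-score curve along pseudotime
#'
#' Means of a per-cell score in `n_bins` sliding windows of width `bin_width`
#' whose centers are evenly spaced to span \[0, 1\], followed by a locally
#' weighted linear (tricube) fit with pointwise normal-approximation 95%
#' confidence bands. Empty windows yield NA means and are interpolated by
#' the fit.
#'
#' @param scores numeric per-cell values.
#' @param pt pseudotime per cell in \[0, 1\].
#' @param n_bins number of windows.
#' @param bin_width window width in pseudotime units.
#' @param span loess span.
#' @return data.frame: center, mean, n, fit, se, lo, hi.
#' @export
binned_module_curve <- function(scores, pt, n_bins = 55, bin_width = 0.10,
                                span = 0.5) {
  stopifnot(length(scores) == length(pt), all(pt >= 0 & pt <= 1, na.rm = TRUE))
  centers <- seq(bin_width / 2, 1 - bin_width / 2, length.out = n_bins)
  means <- ns <- numeric(n_bins)
  for (i in seq_len(n_bins)) {
    inw <- pt >= centers[i] - bin_width / 2 & pt <= centers[i] + bin_width / 2
    ns[i] <- sum(inw)
    means[i] <- if (ns[i] > 0) mean(scores[inw]) else NA_real_
  }
  ok <- !is.na(means)
  d <- data.frame(x = centers[ok], y = means[ok])
  fit <- stats::loess(y ~ x, data = d, span = span, degree = 1,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  pr <- stats::predict(fit, newdata = data.frame(x = centers), se = TRUE)
  data.frame(center = centers, mean = means, n = ns,
             fit = as.numeric(pr$fit), se = as.numeric(pr$se.fit),
             lo = as.numeric(pr$fit - 1.96 * pr$se.fit),
             hi = as.numeric(pr$fit + 1.96 * pr$se.fit))
}
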