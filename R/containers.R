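#' Gene-by-cell expression container
#'
#' Bundles a sparse UMI count matrix (genes x cells) with per-cell metadata
#' (donor, age group, cell type) and a per-gene mitochondrial flag. An
#' optional `norm` slot holds the log-normalized matrix added by
#' [normalize_log()].
#'
#' @param counts genes x cells matrix of non-negative integer counts, with
#'   unique gene symbols as rownames and cell ids as colnames.
#' @param cells data.frame of per-cell metadata with at least `cell_id`;
#'   conventional columns are `donor`, `age_group` (`"young"`/`"aged"`) and
#'   `cell_type`.
#' @param mito logical per-gene mitochondrial flag; default derives it from
#'   the `"MT-"` symbol prefix.
#' @return An object of class `ExpressionMatrix`.
#' @export
ExpressionMatrix <- function(counts, cells, mito = NULL) {
  counts <- as(as(counts, "CsparseMatrix"), "generalMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene symbols as rownames and cell ids as colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene symbols in counts rownames")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate cell ids in counts colnames")
  if (any(counts@x < 0)) stop("negative counts")
  if (any(counts@x != round(counts@x))) stop("non-integer counts")
  cells <- as.data.frame(cells)
  if (!"cell_id" %in% names(cells)) stop("cells metadata needs a cell_id column")
  if (!identical(as.character(cells$cell_id), colnames(counts)))
    stop("cells$cell_id must match counts colnames in order")
  if (is.null(mito)) mito <- startsWith(rownames(counts), "MT-")
  stopifnot(length(mito) == nrow(counts))
  structure(list(counts = counts, cells = cells, mito = mito, norm = NULL),
            class = "ExpressionMatrix")
}

#' Peak-by-cell accessibility container
#'
#' Sparse fragment-count matrix (peaks x cells) plus a BED-style peak table
#' (0-based, half-open coordinates) with per-peak GC fraction.
#'
#' @param counts peaks x cells non-negative integer matrix; rownames are peak
#'   ids, colnames cell ids.
#' @param peaks data.frame with columns `peak_id`, `chrom`, `start`, `end`,
#'   `gc` (0-based half-open; `gc` in \[0,1\]).
#' @param cells data.frame of per-cell metadata with `cell_id`.
#' @return An object of class `AccessibilityMatrix`.
#' @export
AccessibilityMatrix <- function(counts, peaks, cells) {
  counts <- as(as(counts, "CsparseMatrix"), "generalMatrix")
  if (any(counts@x < 0)) stop("negative counts")
  if (any(counts@x != round(counts@x))) stop("non-integer counts")
  peaks <- as.data.frame(peaks)
  need <- c("peak_id", "chrom", "start", "end", "gc")
  if (!all(need %in% names(peaks))) stop("peaks table needs: ", paste(need, collapse = ", "))
  if (!identical(as.character(peaks$peak_id), rownames(counts)))
    stop("peaks$peak_id must match counts rownames in order")
  if (any(peaks$start >= peaks$end)) stop("malformed peak interval: start >= end")
  if (any(peaks$gc < 0 | peaks$gc > 1)) stop("GC fraction outside [0,1]")
  # intervals must be sorted within each chromosome
  by_chr <- split(peaks$start, peaks$chrom)
  if (any(vapply(by_chr, is.unsorted, logical(1))))
    stop("peak intervals not sorted within chromosome")
  cells <- as.data.frame(cells)
  if (!identical(as.character(cells$cell_id), colnames(counts)))
    stop("cells$cell_id must match counts colnames in order")
  structure(list(counts = counts, peaks = peaks, cells = cells),
            class = "AccessibilityMatrix")
}

#' Named gene-set collection with an exclusion list
#'
#' @param sets named list of character vectors of gene symbols.
#' @param exclusion symbols removed from every set before scoring. The default
#'   excludes the canonical senescence markers (p16/CDKN2A, p15/CDKN2B,
#'   p19/CDKN2D, p21/CDKN1A, p27/CDKN1B, PAI-1/SERPINE1) so they remain
#'   available as independent validation of the calls.
#' @return An object of class `GeneSetCollection`.
#' @export
GeneSetCollection <- function(sets, exclusion = default_marker_exclusions()) {
  stopifnot(is.list(sets), !is.null(names(sets)), all(nzchar(names(sets))))
  sets <- lapply(sets, function(s) unique(as.character(s)))
  structure(list(sets = sets, exclusion = unique(as.character(exclusion))),
            class = "GeneSetCollection")
}

#' Canonical senescence-marker exclusion symbols
#'
#' Aliases of P16, P15, P19, P21, P27 and PAI-1, held out of every scored set.
#' @return character vector of symbols.
#' @export
default_marker_exclusions <- function() {
  c("P16", "CDKN2A", "P15", "CDKN2B", "P19", "CDKN2D",
    "P21", "CDKN1A", "P27", "CDKN1B", "PAI-1", "PAI1", "SERPINE1")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d cells (%s)\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$norm)) "raw" else "raw + normalized"))
  invisible(x)
}

#' @export
print.AccessibilityMatrix <- function(x, ...) {
  cat(sprintf("AccessibilityMatrix: %d peaks x %d cells\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf("GeneSetCollection: %d sets (%s); %d excluded symbols\n",
              length(x$sets), paste(names(x$sets), collapse = ", "),
              length(x$exclusion)))
  invisible(x)
}

#' Subset an expression matrix to a set of cells
#' @param expr ExpressionMatrix.
#' @param cell_ids character vector of cell ids to keep (order preserved).
#' @return ExpressionMatrix restricted to those cells.
#' @export
subset_cells <- function(expr, cell_ids) {
  keep <- match(cell_ids, colnames(expr$counts))
  if (anyNA(keep)) stop("unknown cell ids")
  out <- ExpressionMatrix(expr$counts[, keep, drop = FALSE],
                          expr$cells[keep, , drop = FALSE], expr$mito)
  if (!is.null(expr$norm)) out$norm <- expr$norm[, keep, drop = FALSE]
  out
}

# internal: retrieve the normalized matrix or fail loudly
get_norm <- function(expr) {
  if (is.null(expr$norm)) stop("expression matrix is not normalized; run normalize_log() first")
  expr$norm
}
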