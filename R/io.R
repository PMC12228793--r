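#' Read a counts matrix with row/column annotations
#'
#' Reads a Matrix Market counts file plus its row table, column table and,
#' optionally, per-cell metadata, reconstructing either an
#' [ExpressionMatrix()] (rows file with a `symbol` column) or an
#' [AccessibilityMatrix()] (rows file with BED-style peak columns).
#'
#' @param mtx_path Matrix Market (.mtx) file of non-negative integer counts.
#' @param rows_path TSV describing rows: either `symbol` (genes) or
#'   `peak_id, chrom, start, end, gc` (peaks).
#' @param cols_path TSV with a `cell_id` column, one row per matrix column.
#' @param metadata_path optional TSV of per-cell metadata keyed by `cell_id`;
#'   merged onto the column table.
#' @return ExpressionMatrix or AccessibilityMatrix.
#' @export
read_counts <- function(mtx_path, rows_path, cols_path, metadata_path = NULL) {
  check_mtx_header(mtx_path)
  m <- Matrix::readMM(mtx_path)
  rows <- utils::read.delim(rows_path, stringsAsFactors = FALSE)
  cols <- utils::read.delim(cols_path, stringsAsFactors = FALSE)
  if (nrow(rows) != nrow(m) || nrow(cols) != ncol(m))
    stop("dimension mismatch between matrix and row/column tables")
  if (!"cell_id" %in% names(cols)) stop("columns table needs cell_id")
  if (!is.null(metadata_path)) {
    meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
    cols <- merge(cols, meta, by = "cell_id", sort = FALSE)
    cols <- cols[match(colnames_or(cols$cell_id), colnames_or(cols$cell_id)), , drop = FALSE]
  }
  colnames(m) <- cols$cell_id
  if ("symbol" %in% names(rows)) {
    if (anyDuplicated(rows$symbol)) stop("duplicate gene symbols in rows file")
    rownames(m) <- rows$symbol
    ExpressionMatrix(m, cols)
  } else {
    rownames(m) <- rows$peak_id
    AccessibilityMatrix(m, rows, cols)
  }
}

colnames_or <- function(x) as.character(x)

# Validate that the MTX size header agrees with the number of entry lines.
check_mtx_header <- function(path) {
  ln <- readLines(path)
  body <- ln[!startsWith(ln, "%")]
  hdr <- as.numeric(strsplit(trimws(body[1]), "\\s+")[[1]])
  if (length(hdr) != 3) stop("malformed MTX size header")
  n_entries <- sum(nzchar(trimws(body[-1])))
  if (hdr[3] != n_entries)
    stop(sprintf("MTX header declares %d entries but file has %d", hdr[3], n_entries))
  invisible(TRUE)
}

#' Write a counts container to MTX + TSV files
#'
#' Inverse of [read_counts()]; lossless round-trip for counts, row
#' annotations and cell metadata.
#'
#' @param x ExpressionMatrix or AccessibilityMatrix.
#' @param prefix path prefix; writes `<prefix>.mtx`, `<prefix>.rows.tsv`,
#'   `<prefix>.cols.tsv`.
#' @return invisibly, the paths written.
#' @export
write_counts <- function(x, prefix) {
  mtx <- paste0(prefix, ".mtx")
  Matrix::writeMM(x$counts, mtx)
  rows <- if (inherits(x, "ExpressionMatrix")) {
    data.frame(symbol = rownames(x$counts), mito = x$mito)
  } else x$peaks
  utils::write.table(rows, paste0(prefix, ".rows.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(x$cells, paste0(prefix, ".cols.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(mtx, paste0(prefix, ".rows.tsv"), paste0(prefix, ".cols.tsv")))
}

#' Read gene sets from a GMT file
#' @param path GMT file (set name, description, then member symbols, tab-separated).
#' @param exclusion passed to [GeneSetCollection()].
#' @return GeneSetCollection.
#' @export
read_gmt <- function(path, exclusion = default_marker_exclusions()) {
  ln <- readLines(path)
  ln <- ln[nzchar(ln)]
  parts <- strsplit(ln, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[`, character(1), 1)
  GeneSetCollection(sets, exclusion)
}

#' Write gene sets to a GMT file
#' @param gsc GeneSetCollection.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_gmt <- function(gsc, path) {
  ln <- vapply(names(gsc$sets), function(nm) {
    paste(c(nm, "na", gsc$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(ln, path)
  invisible(path)
}

#' Read a BED file of intervals (0-based, half-open)
#' @param path BED3+ file; columns beyond chrom/start/end are kept as `name` etc.
#' @return data.frame with chrom, start, end (and name when present).
#' @export
read_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "name"
  if (any(df$start >= df$end)) stop("malformed interval: start >= end")
  df
}

#' Write peak intervals as BED
#' @param peaks data.frame with chrom, start, end and optionally peak_id.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_bed <- function(peaks, path) {
  df <- peaks[, intersect(c("chrom", "start", "end", "peak_id"), names(peaks))]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a ligand-receptor pair table
#'
#' Expected TSV schema: `pair_id`, `ligand_subunits` (comma-joined symbols),
#' `receptor_subunits`, `pathway`.
#' @param path TSV file.
#' @return data.frame with list-columns `ligand` and `receptor` of subunit symbols.
#' @export
read_lr_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("pair_id", "ligand_subunits", "receptor_subunits", "pathway")
  if (!all(need %in% names(df))) stop("LR table needs columns: ", paste(need, collapse = ", "))
  df$ligand <- strsplit(df$ligand_subunits, ",", fixed = TRUE)
  df$receptor <- strsplit(df$receptor_subunits, ",", fixed = TRUE)
  df
}

#' Write a ligand-receptor pair table
#' @param lr data.frame as returned by [generate_lr_table()] or [read_lr_table()].
#' @param path output TSV.
#' @return invisibly, `path`.
#' @export
write_lr_table <- function(lr, path) {
  out <- data.frame(pair_id = lr$pair_id,
                    ligand_subunits = vapply(lr$ligand, paste, character(1), collapse = ","),
                    receptor_subunits = vapply(lr$receptor, paste, character(1), collapse = ","),
                    pathway = lr$pathway)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSS / gene-span table
#'
#' TSV with columns `chrom, start, end, strand, symbol` (0-based half-open
#' gene spans). The TSS is `start` on the plus strand and `end - 1` on the
#' minus strand.
#' @param path TSV file.
#' @return data.frame with an added `tss` column.
#' @export
read_tss_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "strand", "symbol")
  if (!all(need %in% names(df))) stop("TSS table needs columns: ", paste(need, collapse = ", "))
  if (any(df$start >= df$end)) stop("malformed gene span: start >= end")
  add_tss(df)
}

add_tss <- function(df) {
  df$tss <- ifelse(df$strand == "-", df$end - 1L, df$start)
  df
}
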