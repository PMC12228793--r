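#' Motif accessibility deviations with GC/accessibility-matched backgrounds
#'
#' For each motif, the raw per-cell deviation is d = (x - e) / e where x is
#' the cell's total count in motif-hit peaks and e the expected total under
#' the cell's depth times the motif peaks' global count share. Deviations
#' are z-scored against `n_bg` background peak sets, each drawn (seeded) by
#' replacing every motif peak with one of its nearest neighbours in
#' standardized (GC, mean accessibility) space.
#'
#' @param atac [AccessibilityMatrix()].
#' @param hits motif-hit object: list with `motifs` (motif_id, tf) and `hits`
#'   (logical motif x peak matrix).
#' @param n_bg number of background sets.
#' @param seed sampling seed.
#' @param min_peaks motifs with fewer hit peaks are skipped with a warning.
#' @param pool_size size of the nearest-neighbour pool per peak.
#' @return motif x cell matrix of deviation z-scores.
#' @export
motif_deviation <- function(atac, hits, n_bg = 50, seed = 1, min_peaks = 10,
                            pool_size = 50) {
  X <- atac$counts
  H <- hits$hits
  stopifnot(ncol(H) == nrow(X))
  cell_tot <- Matrix::colSums(X)
  peak_tot <- Matrix::rowSums(X)
  grand <- sum(peak_tot)
  mean_acc <- peak_tot / ncol(X)

  n_hit <- Matrix::rowSums(H != 0)
  use <- which(n_hit >= min_peaks)
  if (length(use) < nrow(H))
    warning(sum(n_hit < min_peaks), " motif(s) with < ", min_peaks, " peaks skipped")
  if (!length(use)) stop("no motif with enough peaks")

  dev_of <- function(idx) {
    x <- Matrix::colSums(X[idx, , drop = FALSE])
    e <- cell_tot * sum(peak_tot[idx]) / grand
    (x - e) / pmax(e, .Machine$double.eps)
  }
  Z <- matrix(NA_real_, length(use), ncol(X),
              dimnames = list(rownames(H)[use], colnames(X)))
  with_seed(seed, {
    for (r in seq_along(use)) {
      idx <- which(as.logical(H[use[r], ] != 0))
      d_obs <- dev_of(idx)
      pools <- matched_peak_pool(atac$peaks$gc, mean_acc, idx, k = pool_size)
      Dbg <- vapply(seq_len(n_bg), function(b) {
        bg <- vapply(pools, function(p) p[sample.int(length(p), 1)], integer(1))
        dev_of(bg)
      }, numeric(ncol(X)))
      mu <- rowMeans(Dbg)
      s <- apply(Dbg, 1, stats::sd)
      Z[r, ] <- (d_obs - mu) / pmax(s, .Machine$double.eps)
    }
  })
  Z
}

#' Rank senescence-associated TF motifs
#'
#' One-sided (greater in senescent cells) rank-sum test on each motif's
#' deviation z-scores, BH-adjusted across motifs.
#'
#' @param z motif x cell deviation matrix from [motif_deviation()].
#' @param calls [uss_classify()] result (or logical senescent flag per cell).
#' @return data.frame sorted by p: motif, effect (mean z Sn - nSn), p, q.
#' @export
senescence_tf_scan <- function(z, calls) {
  sn <- if (inherits(calls, "SenescenceCall")) calls$senescent else calls
  sn <- as.logical(sn)
  stopifnot(length(sn) == ncol(z), any(sn), any(!sn))
  res <- t(apply(z, 1, function(v) {
    if (length(unique(v)) == 1) return(c(effect = 0, p = 1))
    p <- stats::wilcox.test(v[sn], v[!sn], alternative = "greater",
                            exact = FALSE, correct = TRUE)$p.value
    c(effect = mean(v[sn]) - mean(v[!sn]), p = p)
  }))
  out <- data.frame(motif = rownames(z), effect = res[, "effect"], p = res[, "p"],
                    q = stats::p.adjust(res[, "p"], method = "BH"),
                    row.names = NULL)
  out[order(out$p), ]
}

#' Domains of regulatory chromatin: peak-gene association and DORC scores
#'
#' Candidate peaks are those whose centre lies within `half_window` of a
#' gene's TSS (closed boundaries, a 2 x half_window window centred on the
#' TSS). Per candidate, the Spearman correlation between peak counts and the
#' gene's normalized expression across cells is z-scored against `n_bg`
#' GC/accessibility-matched background peaks, giving a one-sided p. The
#' per-cell DORC score of a gene is the summed counts of its significant
#' peaks; genes with at least `n_sig_min` significant peaks are flagged as
#' DORC genes.
#'
#' @param atac [AccessibilityMatrix()] sharing cells with `rna`.
#' @param rna normalized [ExpressionMatrix()].
#' @param tss_table gene table with `symbol` and `tss` ([read_tss_table()]).
#' @param genes genes to score (default: all in `tss_table` and the matrix).
#' @param half_window half-width of the TSS window in bp.
#' @param n_bg background peaks per candidate.
#' @param p_cut significance threshold on the one-sided p.
#' @param n_sig_min significant peaks required for the DORC-gene flag.
#' @param seed background sampling seed.
#' @return list of class `DorcTable`: `pairs` (gene, peak_id, rho, z, p,
#'   significant), `genes` (gene, n_candidates, n_sig, is_dorc), `scores`
#'   (gene x cell DORC score matrix for genes with >= 1 significant peak).
#' @export
build_dorc <- function(atac, rna, tss_table, genes = NULL, half_window = 50000,
                       n_bg = 100, p_cut = 0.05, n_sig_min = 5, seed = 1) {
  nm <- get_norm(rna)
  if (!identical(colnames(atac$counts), colnames(nm)))
    stop("atac and rna must share cell ids in order")
  if (is.null(genes)) genes <- intersect(tss_table$symbol, rownames(nm))
  miss <- setdiff(genes, tss_table$symbol)
  if (length(miss)) {
    warning("gene(s) without TSS skipped: ", paste(miss, collapse = ", "))
    genes <- setdiff(genes, miss)
  }
  genes <- intersect(genes, rownames(nm))
  if (!length(genes)) stop("no scorable genes")
  tss <- tss_table[match(genes, tss_table$symbol), ]

  pk <- atac$peaks
  centre <- floor((pk$start + pk$end) / 2)
  cand <- lapply(seq_along(genes), function(i) {
    which(pk$chrom == tss$chrom[i] & abs(centre - tss$tss[i]) <= half_window)
  })
  names(cand) <- genes
  used_peaks <- sort(unique(unlist(cand)))
  if (!length(used_peaks)) stop("no candidate peaks in any TSS window")

  # Spearman of every peak against every scored gene via standardized ranks
  Zp <- row_rank_z(as.matrix(atac$counts))
  Zg <- row_rank_z(nm[genes, , drop = FALSE])
  RHO <- Zp %*% t(Zg)                      # peaks x genes

  mean_acc <- Matrix::rowMeans(atac$counts)
  pools <- matched_peak_pool(pk$gc, mean_acc, used_peaks, k = max(2 * n_bg, 50))
  names(pools) <- as.character(used_peaks)

  pair_rows <- vector("list", length(genes))
  score_rows <- list()
  gene_rows <- vector("list", length(genes))
  with_seed(seed, {
    for (i in seq_along(genes)) {
      ci <- cand[[i]]
      if (!length(ci)) {
        gene_rows[[i]] <- data.frame(gene = genes[i], n_candidates = 0L,
                                     n_sig = 0L, is_dorc = FALSE)
        next
      }
      rho <- RHO[ci, i]
      z <- p <- rep(NA_real_, length(ci))
      for (j in seq_along(ci)) {
        pool <- pools[[as.character(ci[j])]]
        bg <- pool[sample.int(length(pool), min(n_bg, length(pool)))]
        rb <- RHO[bg, i]
        s <- stats::sd(rb)
        z[j] <- if (is.na(s) || s == 0) NA_real_ else (rho[j] - mean(rb)) / s
        p[j] <- if (is.na(z[j])) 1 else stats::pnorm(z[j], lower.tail = FALSE)
      }
      sig <- !is.na(rho) & p < p_cut
      pair_rows[[i]] <- data.frame(gene = genes[i], peak_id = pk$peak_id[ci],
                                   rho = rho, z = z, p = p, significant = sig)
      n_sig <- sum(sig)
      gene_rows[[i]] <- data.frame(gene = genes[i], n_candidates = length(ci),
                                   n_sig = n_sig, is_dorc = n_sig >= n_sig_min)
      if (n_sig > 0)
        score_rows[[genes[i]]] <- Matrix::colSums(atac$counts[ci[sig], , drop = FALSE])
    }
  })
  scores <- if (length(score_rows)) do.call(rbind, score_rows) else
    matrix(numeric(0), 0, ncol(atac$counts))
  structure(list(pairs = do.call(rbind, pair_rows),
                 genes = do.call(rbind, gene_rows),
                 scores = scores,
                 params = list(half_window = half_window, n_bg = n_bg,
                               p_cut = p_cut, n_sig_min = n_sig_min, seed = seed)),
            class = "DorcTable")
}

#' Signed TF regulation scores over DORC genes
#'
#' For every (TF, gene) pair where the TF's motif hits at least one of the
#' gene's significant peaks: p_motif is the one-sided hypergeometric
#' over-representation of the motif among the gene's significant peaks
#' relative to its candidate-window peaks; rho_TF is the Spearman
#' correlation of TF expression with the gene's per-cell DORC score (p_corr
#' by t approximation); and RS = sign(rho_TF) * sqrt(-log10 p_motif *
#' -log10 p_corr). Positive RS marks an activator, negative a repressor;
#' either evidence at p = 1 forces RS = 0.
#'
#' @param dorc [build_dorc()] result.
#' @param hits motif-hit object (see [motif_deviation()]).
#' @param rna normalized [ExpressionMatrix()] containing TF expression.
#' @return data.frame of class `RegulationTable`: tf, motif, gene, rs,
#'   p_motif, rho_tf, p_corr, n_sig, n_candidates.
#' @export
regulation_score <- function(dorc, hits, rna) {
  nm <- get_norm(rna)
  H <- hits$hits
  motifs <- hits$motifs
  measured <- motifs$tf %in% rownames(nm)
  if (!any(measured)) stop("no motif TF measured in the expression matrix")
  motifs <- motifs[measured, , drop = FALSE]
  scored <- dorc$genes$gene[dorc$genes$n_sig > 0]
  rows <- list()
  for (g in scored) {
    pp <- dorc$pairs[dorc$pairs$gene == g, ]
    cand_idx <- match(pp$peak_id, colnames(H))
    sig_idx <- cand_idx[pp$significant]
    score_g <- dorc$scores[g, ]
    for (mi in seq_len(nrow(motifs))) {
      hit_cand <- as.logical(H[motifs$motif_id[mi], cand_idx] != 0)
      hit_sig <- as.logical(H[motifs$motif_id[mi], sig_idx] != 0)
      k <- sum(hit_sig)
      if (k == 0) next
      K <- sum(hit_cand); N <- length(cand_idx); n <- length(sig_idx)
      if (K == N) {
        # saturated window: the conditional test is degenerate (constant
        # margin), so enrichment is assessed against the genome-wide peak
        # universe instead
        K <- sum(H[motifs$motif_id[mi], ] != 0); N <- ncol(H)
      }
      p_motif <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
      tf_expr <- nm[motifs$tf[mi], ]
      rho <- suppressWarnings(stats::cor(tf_expr, score_g, method = "spearman"))
      if (is.na(rho)) next
      ncell <- length(score_g)
      tstat <- rho * sqrt((ncell - 2) / max(1 - rho^2, 1e-12))
      p_corr <- 2 * stats::pt(abs(tstat), df = ncell - 2, lower.tail = FALSE)
      rs <- sign(rho) * sqrt(max(0, -log10(max(p_motif, 1e-300))) *
                             max(0, -log10(max(p_corr, 1e-300))))
      rows[[length(rows) + 1]] <- data.frame(
        tf = motifs$tf[mi], motif = motifs$motif_id[mi], gene = g, rs = rs,
        p_motif = p_motif, rho_tf = rho, p_corr = p_corr,
        n_sig = n, n_candidates = N)
    }
  }
  if (!length(rows)) return(structure(data.frame(), class = c("RegulationTable", "data.frame")))
  out <- do.call(rbind, rows)
  class(out) <- c("RegulationTable", "data.frame")
  out
}

#' Activated / repressed target sets per TF, with senescence-class scoring
#'
#' Thresholds the regulation table at `tau` (activated: RS > tau; repressed:
#' RS < -tau) and, when an expression matrix and senescence call are given,
#' scores each TF's activated set per cell ([sset_score()]) and summarizes by
#' class.
#'
#' @param reg [regulation_score()] table.
#' @param tau non-negative RS threshold.
#' @param expr optional normalized [ExpressionMatrix()] for set scoring.
#' @param calls optional [uss_classify()] result (or logical per cell).
#' @param alpha weight exponent passed to scoring.
#' @return named list per TF: `activated`, `repressed`, and when scored,
#'   `score_sn`, `score_nsn` (mean activated-set score by class).
#' @export
tf_target_sets <- function(reg, tau = 0, expr = NULL, calls = NULL, alpha = 0.25) {
  stopifnot(tau >= 0)
  if (!nrow(reg)) stop("empty regulation table")
  out <- list()
  for (tf in unique(reg$tf)) {
    sub <- reg[reg$tf == tf, ]
    act <- unique(sub$gene[sub$rs > tau])
    rep_ <- unique(sub$gene[sub$rs < -tau])
    ent <- list(activated = act, repressed = rep_)
    if (!is.null(expr) && length(act)) {
      sc <- score_all(expr, GeneSetCollection(list(set = act), exclusion = character(0)),
                      alpha = alpha)$scores[, 1]
      if (!is.null(calls)) {
        sn <- if (inherits(calls, "SenescenceCall")) calls$senescent else as.logical(calls)
        ent$score_sn <- mean(sc[sn]); ent$score_nsn <- mean(sc[!sn])
      }
      ent$scores <- sc
    }
    out[[tf]] <- ent
  }
  out
}

#' Chromatin-lead dynamics of a gene along pseudotime
#'
#' Cells are ordered by pseudotime and grouped into consecutive bins of
#' `cells_per_bin` cells. Per-bin means of the DORC score and the RNA signal
#' are loess-smoothed against the bin centres, each smoothed curve is
#' clip-normalized to \[0, 1\] by its 1st-99th percentiles, and their
#' difference D = DORC_norm - RNA_norm is reported together with the lead
#' estimate: t50(RNA) - t50(DORC) in bins, where t50 is the first bin whose
#' curve reaches 0.5. A positive lead means chromatin precedes RNA.
#'
#' @param dorc_score_g per-cell DORC score of the gene.
#' @param rna_g per-cell RNA signal (normalized expression).
#' @param pt pseudotime per cell (no NAs).
#' @param cells_per_bin cells per bin (>= 5 bins required).
#' @param span loess span.
#' @return list: `bins` (centre pseudotime, raw and smoothed-normalized
#'   curves, D), `lead_bins`, `chromatin_lead` (logical).
#' @export
dorc_rna_dynamics <- function(dorc_score_g, rna_g, pt, cells_per_bin = 100,
                              span = 0.3) {
  stopifnot(length(dorc_score_g) == length(pt), length(rna_g) == length(pt))
  if (anyNA(pt)) stop("pseudotime contains NA")
  ord <- order(pt)
  nb <- floor(length(pt) / cells_per_bin)
  if (nb < 5) stop("need >= 5 bins; reduce cells_per_bin")
  idx <- ord[seq_len(nb * cells_per_bin)]
  bin <- rep(seq_len(nb), each = cells_per_bin)
  centre <- tapply(pt[idx], bin, mean)
  smooth_norm <- function(v) {
    m <- tapply(v[idx], bin, mean)
    d <- data.frame(x = as.numeric(centre), y = as.numeric(m))
    fit <- stats::predict(stats::loess(y ~ x, d, span = span, degree = 1,
                                       control = stats::loess.control(surface = "direct")),
                          newdata = d)
    qs <- stats::quantile(fit, c(0.01, 0.99), type = 5, names = FALSE)
    if (qs[2] <= qs[1]) return(list(raw = m, norm = rep(0.5, nb)))
    list(raw = m, norm = pmin(1, pmax(0, (fit - qs[1]) / (qs[2] - qs[1]))))
  }
  a <- smooth_norm(dorc_score_g)
  r <- smooth_norm(rna_g)
  t50 <- function(v) {
    w <- which(v >= 0.5)
    if (!length(w)) NA_integer_ else w[1]
  }
  lead <- t50(r$norm) - t50(a$norm)
  list(bins = data.frame(bin = seq_len(nb), centre = as.numeric(centre),
                         dorc_mean = as.numeric(a$raw), rna_mean = as.numeric(r$raw),
                         dorc_norm = a$norm, rna_norm = r$norm,
                         D = a$norm - r$norm),
       lead_bins = as.integer(lead),
       chromatin_lead = isTRUE(lead > 0))
}

#' Annotate peaks against TSS, gene spans and enhancer intervals
#'
#' Promoter: peak centre within 3 kb of the nearest TSS; otherwise gene body
#' when the centre falls inside a gene span; otherwise intergenic. The
#' classes are exclusive and partition the annotated peaks. `distal` flags
#' peaks > 3 kb from every TSS; `enhancer` flags any overlap (half-open)
#' with an H3K27ac interval. Peaks on chromosomes absent from the annotation
#' are skipped with a warning.
#'
#' @param peaks data.frame with chrom, start, end (0-based half-open) and
#'   optionally peak_id.
#' @param tss_table gene table with chrom, start, end, symbol, tss.
#' @param gene_spans optional span table (defaults to `tss_table`).
#' @param h3k27ac optional data.frame of enhancer intervals (chrom, start, end).
#' @param promoter_dist promoter distance threshold in bp.
#' @return data.frame of class `PeakAnnotation`: peak_id, chrom, start, end,
#'   class, distal, enhancer, nearest_gene, dist_tss.
#' @export
annotate_peaks <- function(peaks, tss_table, gene_spans = NULL, h3k27ac = NULL,
                           promoter_dist = 3000) {
  if (is.null(gene_spans)) gene_spans <- tss_table
  if (is.null(peaks$peak_id))
    peaks$peak_id <- sprintf("peak%05d", seq_len(nrow(peaks)))
  known <- peaks$chrom %in% unique(tss_table$chrom)
  if (!all(known)) {
    warning(sum(!known), " peak(s) on chromosomes absent from the annotation skipped: ",
            paste(unique(peaks$chrom[!known]), collapse = ", "))
    peaks <- peaks[known, , drop = FALSE]
  }
  if (!nrow(peaks)) stop("no annotatable peaks")
  centre <- floor((peaks$start + peaks$end) / 2)

  # nearest TSS per peak, ties broken by lexicographic gene symbol
  nearest_gene <- character(nrow(peaks))
  dist_tss <- numeric(nrow(peaks))
  for (ch in unique(peaks$chrom)) {
    sel <- which(peaks$chrom == ch)
    tt <- tss_table[tss_table$chrom == ch, ]
    tt <- tt[order(tt$tss, tt$symbol), ]
    for (i in sel) {
      d <- abs(tt$tss - centre[i])
      dm <- min(d)
      cand <- tt$symbol[d == dm]
      nearest_gene[i] <- sort(cand)[1]
      dist_tss[i] <- dm
    }
  }
  promoter <- dist_tss <= promoter_dist

  # gene-body: centre inside a half-open gene span
  gb <- rep(FALSE, nrow(peaks))
  gr_centre <- GenomicRanges::GRanges(peaks$chrom,
                                      IRanges::IRanges(centre + 1L, centre + 1L))
  gr_spans <- GenomicRanges::GRanges(gene_spans$chrom,
                                     IRanges::IRanges(gene_spans$start + 1L, gene_spans$end))
  gb[S4Vectors::queryHits(GenomicRanges::findOverlaps(gr_centre, gr_spans))] <- TRUE

  cls <- ifelse(promoter, "promoter", ifelse(gb, "gene_body", "intergenic"))
  enh <- rep(FALSE, nrow(peaks))
  if (!is.null(h3k27ac) && nrow(h3k27ac)) {
    gr_pk <- GenomicRanges::GRanges(peaks$chrom,
                                    IRanges::IRanges(peaks$start + 1L, peaks$end))
    gr_h3 <- GenomicRanges::GRanges(h3k27ac$chrom,
                                    IRanges::IRanges(h3k27ac$start + 1L, h3k27ac$end))
    enh[S4Vectors::queryHits(GenomicRanges::findOverlaps(gr_pk, gr_h3))] <- TRUE
  }
  out <- data.frame(peak_id = peaks$peak_id, chrom = peaks$chrom,
                    start = peaks$start, end = peaks$end, class = cls,
                    distal = dist_tss > promoter_dist, enhancer = enh,
                    nearest_gene = nearest_gene, dist_tss = dist_tss,
                    row.names = NULL)
  class(out) <- c("PeakAnnotation", "data.frame")
  out
}

#' Assign TF target genes from annotated binding peaks
#'
#' Promoter peaks contribute their nearest gene; enhancer-flagged distal
#' peaks contribute the nearest TSS within `max_dist` (ties broken by
#' lexicographic symbol in [annotate_peaks()]). The union is de-duplicated;
#' an optional SASP list restricts a second output.
#'
#' @param annotation [annotate_peaks()] result.
#' @param tss_table unused placeholder kept for interface symmetry (nearest
#'   genes are carried on the annotation).
#' @param max_dist maximum TSS distance for enhancer-based assignment.
#' @param sasp optional character vector to intersect with.
#' @return list: `targets` (character), `sasp_targets` (or NULL), `per_peak`
#'   (peak_id, target or NA).
#' @export
assign_targets <- function(annotation, tss_table = NULL, max_dist = 100000,
                           sasp = NULL) {
  tgt <- rep(NA_character_, nrow(annotation))
  tgt[annotation$class == "promoter"] <- annotation$nearest_gene[annotation$class == "promoter"]
  enh_sel <- annotation$enhancer & annotation$distal & annotation$dist_tss <= max_dist
  tgt[enh_sel] <- annotation$nearest_gene[enh_sel]
  targets <- sort(unique(tgt[!is.na(tgt)]))
  list(targets = targets,
       sasp_targets = if (is.null(sasp)) NULL else intersect(targets, sasp),
       per_peak = data.frame(peak_id = annotation$peak_id, target = tgt))
}
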