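#' Configuration for the synthetic multiome generator
#'
#' Defines the study conditions the generator emulates: a two-age-group,
#' multi-donor mixture of cell types with a planted senescent subpopulation,
#' elevated expression dispersion in aged cells, a latent pseudotime with
#' logistic gene/peak trends in which chromatin shifts precede RNA by a
#' configurable lag, planted activator/repressor TF->target structure, and
#' ligand-receptor pairs concentrated in designated sender/receiver types.
#'
#' @param n_cell_types number of cell types (>= 1); the first four are named
#'   MuSC, FAP, EC, SMC.
#' @param n_donors_per_group donors per age group.
#' @param cells_per_donor cells per donor (>= 10).
#' @param n_genes total genes including structural blocks (>= 330).
#' @param n_peaks_per_gene ATAC peaks per gene (>= 2).
#' @param rna_depth_mean expected UMI per cell.
#' @param atac_depth_mean expected ATAC fragments per cell.
#' @param nb_dispersion negative-binomial size (inverse-dispersion) for RNA.
#' @param atac_dispersion negative-binomial size for ATAC.
#' @param sn_fraction planted senescent fraction per (cell type, age group):
#'   either a length-2 numeric `c(young =, aged =)` applied to every type, or
#'   a data.frame with columns `cell_type`, `age_group`, `fraction`.
#' @param sn_effect_log2fc log2 fold elevation of senescence-program genes in
#'   senescent cells (>= 0).
#' @param aged_dispersion_mult multiplier >= 1 on dispersion (1/size) for aged
#'   cells.
#' @param pt_lag_bins chromatin-lead lag for flagged genes, in bins of 1% of
#'   the pseudotime axis (lag in pseudotime units = `pt_lag_bins / 100`).
#' @param mito_fraction expected mitochondrial UMI fraction.
#' @param dorc_rho target count-level Spearman correlation of planted
#'   peak-gene pairs.
#' @param seed integer seed; identical configs reproduce identical output.
#' @return A validated `SimConfig` list.
#' @export
sim_config <- function(n_cell_types = 4, n_donors_per_group = 5,
                       cells_per_donor = 100, n_genes = 600,
                       n_peaks_per_gene = 6, rna_depth_mean = 2500,
                       atac_depth_mean = 5000, nb_dispersion = 10,
                       atac_dispersion = 5,
                       sn_fraction = c(young = 0.08, aged = 0.2),
                       sn_effect_log2fc = 1, aged_dispersion_mult = 1.5,
                       pt_lag_bins = 10, mito_fraction = 0.05,
                       dorc_rho = 0.6, seed = 1) {
  cfg <- list(n_cell_types = as.integer(n_cell_types),
              n_donors_per_group = as.integer(n_donors_per_group),
              cells_per_donor = as.integer(cells_per_donor),
              n_genes = as.integer(n_genes),
              n_peaks_per_gene = as.integer(n_peaks_per_gene),
              rna_depth_mean = rna_depth_mean,
              atac_depth_mean = atac_depth_mean,
              nb_dispersion = nb_dispersion,
              atac_dispersion = atac_dispersion,
              sn_fraction = sn_fraction,
              sn_effect_log2fc = sn_effect_log2fc,
              aged_dispersion_mult = aged_dispersion_mult,
              pt_lag_bins = pt_lag_bins,
              mito_fraction = mito_fraction,
              dorc_rho = dorc_rho,
              seed = as.integer(seed))
  stopifnot(cfg$n_cell_types >= 1, cfg$n_donors_per_group >= 1,
            cfg$n_peaks_per_gene >= 2,
            cfg$rna_depth_mean > 0, cfg$atac_depth_mean > 0,
            cfg$nb_dispersion > 0, cfg$atac_dispersion > 0,
            cfg$mito_fraction >= 0, cfg$mito_fraction < 1,
            cfg$dorc_rho >= 0, cfg$dorc_rho < 1)
  if (cfg$sn_effect_log2fc < 0) stop("sn_effect_log2fc must be >= 0")
  if (cfg$cells_per_donor < 10) stop("cells_per_donor must be >= 10")
  if (cfg$aged_dispersion_mult < 1) stop("aged_dispersion_mult must be >= 1")
  if (cfg$n_genes < 330) stop("n_genes must be >= 330 to host the structural gene blocks")
  fr <- sn_fraction_table_cfg(cfg)
  if (any(fr$fraction < 0 | fr$fraction > 1)) stop("sn_fraction outside [0,1]")
  class(cfg) <- "SimConfig"
  cfg
}

# canonical cell-type names
sim_cell_types <- function(k) {
  base <- c("MuSC", "FAP", "EC", "SMC")
  if (k <= 4) base[seq_len(k)] else c(base, sprintf("CT%02d", seq_len(k - 4)))
}

# expand the sn_fraction argument into a full (cell_type, age_group) table
sn_fraction_table_cfg <- function(cfg) {
  types <- sim_cell_types(cfg$n_cell_types)
  sf <- cfg$sn_fraction
  if (is.data.frame(sf)) {
    full <- expand.grid(cell_type = types, age_group = c("young", "aged"),
                        stringsAsFactors = FALSE)
    full$fraction <- 0
    key <- paste(sf$cell_type, sf$age_group)
    m <- match(paste(full$cell_type, full$age_group), key)
    full$fraction[!is.na(m)] <- sf$fraction[m[!is.na(m)]]
    full
  } else {
    if (is.null(names(sf)) || !all(c("young", "aged") %in% names(sf)))
      stop("sn_fraction vector needs named entries young and aged")
    expand.grid(cell_type = types, age_group = c("young", "aged"),
                stringsAsFactors = FALSE) |>
      transform(fraction = ifelse(age_group == "aged", sf[["aged"]], sf[["young"]]))
  }
}

# fixed gene panel layout: index vectors by block, plus symbols
sim_gene_panel <- function(cfg) {
  types <- sim_cell_types(cfg$n_cell_types)
  sym <- character(0); blocks <- list()
  add <- function(name, symbols) {
    idx <- length(sym) + seq_along(symbols)
    sym <<- c(sym, symbols)
    blocks[[name]] <<- idx
    idx
  }
  add("mito", sprintf("MT-G%02d", 1:10))
  for (t in types) add(paste0("marker.", t), sprintf("MRK-%s-%d", t, 1:8))
  add("SenMayo", sprintf("SM-%03d", 1:25))
  add("CellAge", sprintf("CA-%03d", 1:25))
  add("GenAge", sprintf("GA-%03d", 1:25))
  add("SenescenceEigengene", sprintf("SE-%03d", 1:25))
  add("excluded", c("CDKN2A", "CDKN2B", "CDKN2D", "CDKN1A", "CDKN1B", "SERPINE1"))
  add("SASP", sprintf("SASP-%02d", 1:30))
  add("cellcycle", sprintf("CCG-%02d", 1:15))
  add("invariant", sprintf("INV-%02d", 1:40))
  add("trend", sprintf("TRD-%02d", 1:30))
  tfs <- c("TFA1", "TFA2", "TFR1", "TFR2")
  add("tf", tfs)
  for (tf in tfs) add(paste0("target.", tf), sprintf("TGT-%s-%d", tf, 1:5))
  add("dorc", sprintf("DRC-%02d", 1:15))
  add("lead", sprintf("LEAD-%02d", 1:10))
  add("receptor", sprintf("RCP-%02d", 1:6))
  n_fill <- cfg$n_genes - length(sym)
  if (n_fill > 0) add("filler", sprintf("FIL-%04d", seq_len(n_fill)))
  list(symbols = sym, blocks = blocks, types = types, tfs = tfs,
       tf_sign = c(TFA1 = 1, TFA2 = 1, TFR1 = -1, TFR2 = -1))
}

# logistic trend in pseudotime: low + span * plogis((u - mid)/scale)
logi_trend <- function(u, mid, scale = 0.18, low = 0.3, span = 2.7, sign = 1) {
  low + span * stats::plogis(sign * (u - mid) / scale)
}

# count-Spearman -> latent-copula correlation (tie attenuation, measured once
# on the generator's default marginals)
COPULA_ATTEN <- 0.92

#' Generate a paired RNA + ATAC synthetic multiome with planted truth
#'
#' Draws negative-binomial (Gamma-Poisson) UMI and fragment counts over a
#' structured gene/peak panel: cell-type marker programs, a senescence/SASP
#' program elevated `2^sn_effect_log2fc`-fold in planted senescent cells,
#' logistic pseudotime trends whose chromatin midpoint precedes RNA for
#' flagged genes, copula-coupled peak-gene pairs at a target Spearman
#' correlation, activator/repressor TF->target structure mirrored in a
#' motif-hit matrix, and ligand/receptor genes concentrated in designated
#' sender/receiver cell types. Fully deterministic under `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with elements `rna` ([ExpressionMatrix()]), `atac`
#'   ([AccessibilityMatrix()]), `gene_sets` ([GeneSetCollection()]), `truth`
#'   (planted ground-truth record), `motif_hits` (list: `motifs` table and
#'   logical motif x peak matrix), `tss` (gene span/TSS table) and `config`.
#' @export
generate_multiome <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  panel <- sim_gene_panel(config)
  with_seed(config$seed, generate_multiome_impl(config, panel))
}

generate_multiome_impl <- function(cfg, panel) {
  types <- panel$types
  G <- cfg$n_genes
  donors <- c(sprintf("Y%02d", seq_len(cfg$n_donors_per_group)),
              sprintf("A%02d", seq_len(cfg$n_donors_per_group)))
  groups <- rep(c("young", "aged"), each = cfg$n_donors_per_group)
  cells <- do.call(rbind, lapply(seq_along(donors), function(d) {
    data.frame(cell_id = sprintf("%s_c%04d", donors[d], seq_len(cfg$cells_per_donor)),
               donor = donors[d], age_group = groups[d],
               cell_type = rep_len(types, cfg$cells_per_donor),
               stringsAsFactors = FALSE)
  }))
  n <- nrow(cells)

  # planted senescent flags per (type, group) stratum
  fr <- sn_fraction_table_cfg(cfg)
  key <- paste(cells$cell_type, cells$age_group)
  frac <- fr$fraction[match(key, paste(fr$cell_type, fr$age_group))]
  sn <- stats::rbinom(n, 1, frac) == 1

  # latent pseudotime: aged cells shifted later; with equal group sizes the
  # pooled distribution is exactly uniform, so equal-cell bins downstream
  # correspond to equal pseudotime spans
  u <- ifelse(cells$age_group == "aged",
              stats::rbeta(n, 2, 1), stats::rbeta(n, 1, 2))

  # latent TF activities
  a <- matrix(stats::rnorm(length(panel$tfs) * n), nrow = length(panel$tfs),
              dimnames = list(panel$tfs, cells$cell_id))

  # gene base abundances and peak layout
  base_w <- stats::rlnorm(G, 0, 0.8)
  base_w[panel$blocks$invariant] <- exp(1.8)   # housekeeping-like: high, constant
  peaks <- sim_peak_table(cfg, panel)
  peak_w <- stats::rlnorm(nrow(peaks), 0, 0.5)
  peak_w[peaks$planted] <- peak_w[peaks$planted] * 2

  # copula genes: dorc + lead blocks share latents with their planted peaks
  cop_idx <- c(panel$blocks$dorc, panel$blocks$lead)
  rho_lat <- min(0.995, cfg$dorc_rho / COPULA_ATTEN)
  delta <- cfg$pt_lag_bins / 100

  sn_prog <- sn_program_idx(panel)
  lr <- planted_lr_pairs(panel, types)

  theta_rna <- cfg$nb_dispersion / ifelse(cells$age_group == "aged", cfg$aged_dispersion_mult, 1)
  theta_atac <- cfg$atac_dispersion / ifelse(cells$age_group == "aged", cfg$aged_dispersion_mult, 1)

  chunk <- 2000L
  starts <- seq(1L, n, by = chunk)
  rna_parts <- vector("list", length(starts))
  atac_parts <- vector("list", length(starts))
  for (ci in seq_along(starts)) {
    j <- starts[ci]:min(starts[ci] + chunk - 1L, n)
    cl <- cells[j, , drop = FALSE]
    nc <- length(j)

    # shared copula latents for this chunk (one row per copula gene)
    L <- matrix(stats::rnorm(length(cop_idx) * nc), nrow = length(cop_idx))

    ## ---- RNA means ----
    W <- matrix(base_w, G, nc)
    for (t in types) {
      mt <- panel$blocks[[paste0("marker.", t)]]
      W[mt, cl$cell_type == t] <- W[mt, cl$cell_type == t] * 6
    }
    W[sn_prog, sn[j]] <- W[sn_prog, sn[j]] * 2^cfg$sn_effect_log2fc
    W[panel$blocks$cellcycle, ] <- W[panel$blocks$cellcycle, ] *
      rep(logi_trend(u[j], 0.5, sign = -1), each = length(panel$blocks$cellcycle))
    W[panel$blocks$trend, ] <- W[panel$blocks$trend, ] *
      rep(logi_trend(u[j], 0.5), each = length(panel$blocks$trend))
    W[panel$blocks$lead, ] <- W[panel$blocks$lead, ] *
      rep(logi_trend(u[j], 0.55, scale = 0.10), each = length(panel$blocks$lead))
    for (tf in panel$tfs) {
      W[panel$blocks$tf[match(tf, panel$tfs)], ] <-
        W[panel$blocks$tf[match(tf, panel$tfs)], ] * exp(0.8 * a[tf, j])
      tg <- panel$blocks[[paste0("target.", tf)]]
      W[tg, ] <- W[tg, ] * rep(exp(0.7 * panel$tf_sign[[tf]] * a[tf, j]), each = length(tg))
    }
    for (p in seq_len(nrow(lr))) {
      li <- match(lr$ligand[p], panel$symbols)
      ri <- match(lr$receptor[p], panel$symbols)
      W[li, cl$cell_type == lr$sender[p]] <- W[li, cl$cell_type == lr$sender[p]] * 8
      W[ri, cl$cell_type == lr$receiver[p]] <- W[ri, cl$cell_type == lr$receiver[p]] * 8
    }
    mi <- panel$blocks$mito
    msplit <- base_w[mi] / sum(base_w[mi])
    non_mito_mean <- mean(colSums(W[-mi, , drop = FALSE]))
    W[mi, ] <- msplit * non_mito_mean * cfg$mito_fraction / (1 - cfg$mito_fraction)

    # constant normalizer (not per-cell): per-gene means then depend only on
    # the gene's own multipliers, keeping every marginal exactly NB
    mu <- W * (cfg$rna_depth_mean / mean(colSums(W)))
    th <- rep(theta_rna[j], each = G)
    X <- matrix(stats::rnbinom(G * nc, mu = as.numeric(mu), size = th), G, nc)
    # copula genes: redraw from shared latents, preserving NB marginals
    for (k in seq_along(cop_idx)) {
      g <- cop_idx[k]
      X[g, ] <- stats::qnbinom(stats::pnorm(L[k, ]), mu = mu[g, ], size = theta_rna[j])
    }
    rna_parts[[ci]] <- methods::as(X, "CsparseMatrix")

    ## ---- ATAC means ----
    P <- nrow(peaks)
    V <- matrix(peak_w, P, nc)
    sn_peaks <- peaks$gene_idx %in% sn_prog
    V[sn_peaks, sn[j]] <- V[sn_peaks, sn[j]] * 2^cfg$sn_effect_log2fc
    for (tf in panel$tfs) {
      tg <- panel$blocks[[paste0("target.", tf)]]
      pk <- which(peaks$planted & peaks$gene_idx %in% tg)
      V[pk, ] <- V[pk, ] * rep(exp(0.7 * panel$tf_sign[[tf]] * a[tf, j]), each = length(pk))
    }
    lead_pk <- which(peaks$planted & peaks$gene_idx %in% panel$blocks$lead)
    V[lead_pk, ] <- V[lead_pk, ] *
      rep(logi_trend(u[j], 0.55 - delta, scale = 0.10), each = length(lead_pk))

    muA <- V * (cfg$atac_depth_mean / mean(colSums(V)))
    thA <- rep(theta_atac[j], each = P)
    Y <- matrix(stats::rnbinom(P * nc, mu = as.numeric(muA), size = thA), P, nc)
    for (k in seq_along(cop_idx)) {
      g <- cop_idx[k]
      for (pk in which(peaks$planted & peaks$gene_idx == g)) {
        zp <- rho_lat * L[k, ] + sqrt(1 - rho_lat^2) * stats::rnorm(nc)
        Y[pk, ] <- stats::qnbinom(stats::pnorm(zp), mu = muA[pk, ], size = theta_atac[j])
      }
    }
    atac_parts[[ci]] <- methods::as(Y, "CsparseMatrix")
  }

  rna_counts <- do.call(cbind, rna_parts)
  dimnames(rna_counts) <- list(panel$symbols, cells$cell_id)
  atac_counts <- do.call(cbind, atac_parts)
  dimnames(atac_counts) <- list(peaks$peak_id, cells$cell_id)

  rna <- ExpressionMatrix(rna_counts, cells)
  atac <- AccessibilityMatrix(atac_counts, peaks[, c("peak_id", "chrom", "start", "end", "gc")], cells)
  gene_sets <- sim_gene_sets(panel)
  motif_hits <- sim_motif_hits(panel, peaks)
  tss <- sim_tss_table(cfg, panel)

  truth <- list(
    cells = cbind(cells, senescent = sn, pseudotime = u),
    senescent = stats::setNames(sn, cells$cell_id),
    pseudotime = stats::setNames(u, cells$cell_id),
    tf_sign = panel$tf_sign,
    tf_targets = stats::setNames(
      lapply(panel$tfs, function(tf) panel$symbols[panel$blocks[[paste0("target.", tf)]]]),
      panel$tfs),
    planted_peaks = split(peaks$peak_id[peaks$planted],
                          panel$symbols[peaks$gene_idx[peaks$planted]]),
    null_peaks = peaks$peak_id[!peaks$planted],
    dorc_genes = panel$symbols[panel$blocks$dorc],
    lead_genes = panel$symbols[panel$blocks$lead],
    chromatin_lag_bins = stats::setNames(
      rep(cfg$pt_lag_bins, length(panel$blocks$lead)),
      panel$symbols[panel$blocks$lead]),
    # mitochondrial genes hold a constant expression share, so they belong to
    # the invariant list alongside the housekeeping block
    invariant_genes = c(panel$symbols[panel$blocks$invariant],
                        panel$symbols[panel$blocks$mito]),
    sn_program = panel$symbols[sn_prog],
    lr_planted = lr,
    ordering_genes = panel$symbols[panel$blocks$trend],
    # decoy LR pairs must be expressed (a decoy is an unstructured pair, not
    # an absent transcript): restrict the pool to filler genes whose base
    # abundance makes them detectable at the configured depth
    decoy_pool = panel$symbols[panel$blocks$filler][base_w[panel$blocks$filler] >= 0.5]
  )

  list(rna = rna, atac = atac, gene_sets = gene_sets, truth = truth,
       motif_hits = motif_hits, tss = tss, config = cfg)
}

# the genes elevated in senescent cells: four senescence sets + SASP + the
# held-out canonical markers
sn_program_idx <- function(panel) {
  unique(c(panel$blocks$SenMayo, panel$blocks$CellAge, panel$blocks$GenAge,
           panel$blocks$SenescenceEigengene, panel$blocks$SASP, panel$blocks$excluded))
}

# planted LR pairs: ligand = first SASP genes, receptor = RCP block;
# senders/receivers rotate over cell types
planted_lr_pairs <- function(panel, types) {
  k <- length(panel$blocks$receptor)
  data.frame(
    pair_id = sprintf("PLANT-%02d", seq_len(k)),
    ligand = panel$symbols[panel$blocks$SASP[seq_len(k)]],
    receptor = panel$symbols[panel$blocks$receptor],
    sender = types[(seq_len(k) - 1) %% length(types) + 1],
    receiver = types[seq_len(k) %% length(types) + 1],
    pathway = rep(c("SASP-CXCL", "SASP-MMP"), length.out = k),
    stringsAsFactors = FALSE)
}

# gene spans: 150 genes per synthetic chromosome, 200 kb apart, plus strand
sim_tss_table <- function(cfg, panel) {
  g <- seq_len(cfg$n_genes)
  chrom <- sprintf("chrS%d", (g - 1) %/% 150 + 1)
  tss <- ((g - 1) %% 150) * 200000 + 10000
  add_tss(data.frame(chrom = chrom, start = tss, end = tss + 20000,
                     strand = "+", symbol = panel$symbols,
                     stringsAsFactors = FALSE))
}

# peak table: n_peaks_per_gene peaks in each gene's TSS window; all but the
# last peak of structured genes are "planted" (eligible for coupling)
sim_peak_table <- function(cfg, panel) {
  tss <- sim_tss_table(cfg, panel)
  offs <- round(seq(500, 48000, length.out = cfg$n_peaks_per_gene))
  gene_idx <- rep(seq_len(cfg$n_genes), each = cfg$n_peaks_per_gene)
  off <- rep(offs, cfg$n_genes)
  start <- tss$tss[gene_idx] + off
  structured <- c(panel$blocks$dorc, panel$blocks$lead,
                  unlist(panel$blocks[paste0("target.", panel$tfs)], use.names = FALSE))
  planted <- gene_idx %in% structured &
    rep(seq_len(cfg$n_peaks_per_gene), cfg$n_genes) < cfg$n_peaks_per_gene
  data.frame(
    peak_id = sprintf("peak_%s_%d", panel$symbols[gene_idx],
                      rep(seq_len(cfg$n_peaks_per_gene), cfg$n_genes)),
    chrom = tss$chrom[gene_idx], start = start, end = start + 500L,
    gc = round(stats::runif(length(start), 0.3, 0.7), 4),
    gene_idx = gene_idx, planted = planted,
    stringsAsFactors = FALSE)
}

# the GMT the scorer consumes; the held-out markers are appended to every
# senescence set so the exclusion rule is exercised
sim_gene_sets <- function(panel) {
  ex <- panel$symbols[panel$blocks$excluded]
  sets <- list(
    SenMayo = c(panel$symbols[panel$blocks$SenMayo], ex),
    CellAge = c(panel$symbols[panel$blocks$CellAge], ex),
    GenAge = c(panel$symbols[panel$blocks$GenAge], ex),
    SenescenceEigengene = c(panel$symbols[panel$blocks$SenescenceEigengene], ex),
    SASP = panel$symbols[panel$blocks$SASP],
    CellCycle = panel$symbols[panel$blocks$cellcycle])
  GeneSetCollection(sets)
}

# motif x peak hits: each TF hits the planted peaks of its targets plus a 5%
# random background; the first activator additionally hits senescence-program
# peaks (a senescence-open motif)
sim_motif_hits <- function(panel, peaks) {
  P <- nrow(peaks)
  tfs <- panel$tfs
  H <- matrix(FALSE, length(tfs), P, dimnames = list(paste0("M_", tfs), peaks$peak_id))
  for (tf in tfs) {
    tg <- panel$blocks[[paste0("target.", tf)]]
    H[paste0("M_", tf), peaks$planted & peaks$gene_idx %in% tg] <- TRUE
    H[paste0("M_", tf), ] <- H[paste0("M_", tf), ] | (stats::runif(P) < 0.05)
  }
  sn_prog <- sn_program_idx(panel)
  H["M_TFA1", peaks$gene_idx %in% sn_prog] <- TRUE
  list(motifs = data.frame(motif_id = paste0("M_", tfs), tf = tfs,
                           stringsAsFactors = FALSE),
       hits = methods::as(H, "CsparseMatrix"))
}

#' Generate a ligand-receptor table with planted and decoy pairs
#'
#' Emits the planted sender/receiver pairs recorded in the truth record plus
#' `n_decoys` decoy pairs built from unstructured filler genes, whose
#' communication p-values are null-distributed. Decoy pairs use disjoint gene
#' pairs when the filler pool allows, otherwise genes are reused.
#'
#' @param config a [sim_config()].
#' @param truth the truth record from [generate_multiome()].
#' @param n_decoys number of decoy pairs.
#' @return data.frame with columns `pair_id`, `ligand`, `receptor` (single
#'   subunit list-columns), `pathway`, `planted`.
#' @export
generate_lr_table <- function(config, truth, n_decoys = 20) {
  stopifnot(inherits(config, "SimConfig"))
  panel <- sim_gene_panel(config)
  fill <- panel$symbols[panel$blocks$filler]
  if (!is.null(truth$decoy_pool) && length(truth$decoy_pool) >= 2)
    fill <- truth$decoy_pool
  if (length(fill) < 2) stop("no filler genes available for decoy pairs")
  planted <- truth$lr_planted
  dec <- with_seed(config$seed + 101L, {
    if (length(fill) >= 2 * n_decoys) {
      pick <- sample(fill, 2 * n_decoys)
      cbind(pick[seq_len(n_decoys)], pick[n_decoys + seq_len(n_decoys)])
    } else {
      t(vapply(seq_len(n_decoys), function(i) sample(fill, 2), character(2)))
    }
  })
  out <- data.frame(
    pair_id = c(planted$pair_id, sprintf("DECOY-%03d", seq_len(n_decoys))),
    pathway = c(planted$pathway, sprintf("Null%d", (seq_len(n_decoys) - 1) %% 4 + 1)),
    planted = c(rep(TRUE, nrow(planted)), rep(FALSE, n_decoys)),
    stringsAsFactors = FALSE)
  out$ligand <- as.list(c(planted$ligand, dec[, 1]))
  out$receptor <- as.list(c(planted$receptor, dec[, 2]))
  out
}

#' Small QC fixture with cells violating each filter rule
#'
#' Builds a <= 50-cell paired RNA/ATAC fixture in which individual cells are
#' constructed to violate exactly one quality rule each (low/high UMI, high or
#' boundary mitochondrial percentage, low/high/boundary ATAC totals), together
#' with the set of cell ids a correct filter must retain. The expected
#' survivors are derived from the planted totals, not by running the filter.
#'
#' @param seed integer seed for scattering counts across genes.
#' @return list with `rna`, `atac` and `expected_pass` (character cell ids).
#' @export
generate_qc_fixture <- function(seed = 1) {
  design <- data.frame(
    cell_id = sprintf("qc%02d", 1:12),
    umi = c(2500, 500, 45000, 1000, 1001, 39999, 40000, 2500, 2500, 2500, 2500, 2500),
    mito_pct = c(5, 5, 5, 5, 5, 5, 5, 25, 20, 19.96, 5, 5),
    atac = c(5000, 5000, 5000, 5000, 5000, 5000, 5000, 5000, 5000, 5000, 800, 150000),
    stringsAsFactors = FALSE)
  # mitochondrial counts are integers, so the expected survivors are derived
  # from the realized percentage, not the nominal one
  design$mito_counts <- round(design$umi * design$mito_pct / 100)
  realized_pct <- 100 * design$mito_counts / design$umi
  # survivors: strict >1000 & <40000 UMI, mito% < 20, >1000 & <100000 ATAC
  design$pass <- design$umi > 1000 & design$umi < 40000 &
    realized_pct < 20 & design$atac > 1000 & design$atac < 100000
  genes <- c(sprintf("G%02d", 1:20), sprintf("MT-F%d", 1:5))
  mito_idx <- 21:25
  n <- nrow(design)
  X <- matrix(0L, length(genes), n, dimnames = list(genes, design$cell_id))
  with_seed(seed, {
    for (i in seq_len(n)) {
      m <- design$mito_counts[i]
      r <- design$umi[i] - m
      X[mito_idx, i] <- as.integer(stats::rmultinom(1, m, rep(1, 5)))
      X[1:20, i] <- as.integer(stats::rmultinom(1, r, rep(1, 20)))
    }
  })
  meta <- data.frame(cell_id = design$cell_id, donor = "D1", age_group = "young",
                     cell_type = "MuSC", stringsAsFactors = FALSE)
  rna <- ExpressionMatrix(X, meta)
  pk <- data.frame(peak_id = sprintf("pkq%02d", 1:10), chrom = "chrS1",
                   start = seq(0, 9000, by = 1000), end = seq(500, 9500, by = 1000),
                   gc = 0.5, stringsAsFactors = FALSE)
  Y <- matrix(0L, 10, n, dimnames = list(pk$peak_id, design$cell_id))
  with_seed(seed + 1L, {
    for (i in seq_len(n)) Y[, i] <- as.integer(stats::rmultinom(1, design$atac[i], rep(1, 10)))
  })
  atac <- AccessibilityMatrix(Y, pk, meta)
  list(rna = rna, atac = atac, expected_pass = design$cell_id[design$pass])
}

#' Write a generated multiome to standard on-disk formats
#'
#' MTX + row/column TSVs for both matrices, GMT for gene sets, BED for peaks,
#' TSV for the TSS table and cell metadata, JSON for config and truth record.
#'
#' @param sim output of [generate_multiome()].
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
write_multiome <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_counts(sim$rna, file.path(dir, "rna"))
  write_counts(sim$atac, file.path(dir, "atac"))
  write_gmt(sim$gene_sets, file.path(dir, "gene_sets.gmt"))
  write_bed(sim$atac$peaks, file.path(dir, "peaks.bed"))
  utils::write.table(sim$tss, file.path(dir, "tss.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$rna$cells, file.path(dir, "cell_metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- unclass(sim$config)
  jsonlite::write_json(cfg, file.path(dir, "sim_config.json"), auto_unbox = TRUE)
  tr <- sim$truth
  tr$cells <- NULL
  jsonlite::write_json(tr, file.path(dir, "truth.json"), auto_unbox = TRUE)
  utils::write.table(sim$truth$cells, file.path(dir, "truth_cells.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
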