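test_that("motif deviations are centred, deterministic, and senescence-sensitive", {
  sim <- sim_default_small()
  z <- motif_deviation(sim$atac, sim$motif_hits, n_bg = 30, seed = 21)
  z2 <- motif_deviation(sim$atac, sim$motif_hits, n_bg = 30, seed = 21)
  expect_identical(z, z2)

  sn <- sim$truth$senescent[colnames(z)]
  expect_gt(mean(z["M_TFA1", sn]), mean(z["M_TFA1", !sn]))

  # a cell whose counts are proportional to the global peak profile has
  # raw deviation ~ 0 for every motif
  pk_tot <- Matrix::rowSums(sim$atac$counts)
  prop_cell <- round(pk_tot / 50)
  idx <- which(as.logical(sim$motif_hits$hits["M_TFA2", ] != 0))
  x <- sum(prop_cell[idx])
  e <- sum(prop_cell) * sum(pk_tot[idx]) / sum(pk_tot)
  expect_lt(abs((x - e) / e), 0.05)
})

test_that("too-small motifs are skipped and the senescence scan is calibrated", {
  sim <- sim_default_small()
  tiny <- sim$motif_hits
  tiny$hits[2, ] <- FALSE
  tiny$hits[2, 1:3] <- TRUE
  expect_warning(z <- motif_deviation(sim$atac, tiny, n_bg = 20, seed = 1), "skipped")
  expect_false("M_TFA2" %in% rownames(z))

  z_full <- motif_deviation(sim$atac, sim$motif_hits, n_bg = 30, seed = 21)
  sn <- sim$truth$senescent[colnames(z_full)]
  scan <- senescence_tf_scan(z_full, sn)
  expect_equal(scan$motif[1], "M_TFA1")
  expect_lt(scan$q[1], 0.05)

  # all-equal deviations give p = 1
  z_const <- rbind(z_full, M_X = rep(1, ncol(z_full)))
  scan2 <- senescence_tf_scan(z_const, sn)
  expect_equal(scan2$p[scan2$motif == "M_X"], 1)

  # permuted labels: calibrated type-I error over repeats
  set.seed(22)
  fp <- vapply(1:20, function(i) {
    s <- senescence_tf_scan(z_full, sample(sn))
    sum(s$q < 0.05)
  }, numeric(1))
  expect_lte(mean(fp) / nrow(z_full), 0.05 + 2 * sqrt(0.05 * 0.95 / (20 * nrow(z_full))))
})

test_that("DORC recovery: planted pairs, null calibration, boundary and symmetry", {
  sim <- sim_single_type()
  rna <- cached_sim("single_type_norm", function() norm_rna(sim_single_type()))
  dorc <- cached_sim("single_type_dorc", function() {
    sim <- sim_single_type()
    build_dorc(sim$atac, cached_sim("single_type_norm", function() norm_rna(sim_single_type())),
               sim$tss, genes = c(sim$truth$dorc_genes,
                                  unlist(sim$truth$tf_targets, use.names = FALSE)),
               seed = 23)
  })
  pl <- dorc$pairs[dorc$pairs$gene %in% sim$truth$dorc_genes &
                   dorc$pairs$peak_id %in% unlist(sim$truth$planted_peaks), ]
  expect_true(all(pl$rho > 0))
  expect_lte(median(abs(pl$rho - sim$config$dorc_rho)), 0.15)
  expect_gte(mean(pl$significant), 0.95)

  np <- dorc$pairs[dorc$pairs$peak_id %in% sim$truth$null_peaks, ]
  fpr <- mean(np$p < 0.05)
  expect_lte(fpr, 0.05 + 2 * sqrt(0.05 * 0.95 / nrow(np)))

  # DORC scores are non-negative sums and n_sig matches the pair table
  expect_true(all(dorc$scores >= 0))
  g1 <- dorc$genes$gene[1]
  expect_equal(dorc$genes$n_sig[1],
               sum(dorc$pairs$significant[dorc$pairs$gene == g1]))

  # permuting cells identically in both assays leaves rho unchanged
  perm <- rev(seq_len(ncol(rna$counts)))
  atac_p <- AccessibilityMatrix(sim$atac$counts[, perm], sim$atac$peaks,
                                sim$atac$cells[perm, ])
  rna_p <- subset_cells(rna, colnames(rna$counts)[perm])
  dorc_p <- build_dorc(atac_p, rna_p, sim$tss, genes = sim$truth$dorc_genes[1:3],
                       seed = 23)
  ref <- dorc$pairs[dorc$pairs$gene %in% sim$truth$dorc_genes[1:3], ]
  expect_equal(dorc_p$pairs$rho, ref$rho, tolerance = 1e-12)

  # closed window boundary: a peak centred exactly at TSS + half_window counts
  expect_warning(
    d2 <- build_dorc(sim$atac, rna, sim$tss, genes = c(sim$truth$dorc_genes[1], "GHOST"),
                     seed = 1),
    "GHOST")
  cand <- d2$pairs[d2$pairs$gene == sim$truth$dorc_genes[1], ]
  centre <- floor((sim$atac$peaks$start + sim$atac$peaks$end) / 2)
  tssv <- sim$tss$tss[match(sim$truth$dorc_genes[1], sim$tss$symbol)]
  in_window <- sim$atac$peaks$peak_id[
    sim$atac$peaks$chrom == sim$tss$chrom[match(sim$truth$dorc_genes[1], sim$tss$symbol)] &
      abs(centre - tssv) <= 50000]
  expect_setequal(cand$peak_id, in_window)
})

test_that("regulation scores recover planted signs and obey the forced zero", {
  sim <- sim_single_type()
  rna <- cached_sim("single_type_norm", function() norm_rna(sim_single_type()))
  dorc <- cached_sim("single_type_dorc", function() {
    sim <- sim_single_type()
    build_dorc(sim$atac, cached_sim("single_type_norm", function() norm_rna(sim_single_type())),
               sim$tss, genes = c(sim$truth$dorc_genes,
                                  unlist(sim$truth$tf_targets, use.names = FALSE)),
               seed = 23)
  })
  reg <- regulation_score(dorc, sim$motif_hits, rna)
  planted <- reg[mapply(function(tf, g) g %in% sim$truth$tf_targets[[tf]],
                        reg$tf, reg$gene), ]
  expect_gte(mean(sign(planted$rs) == sim$truth$tf_sign[planted$tf]), 0.9)
  act <- planted[sim$truth$tf_sign[planted$tf] == 1, ]
  repr <- planted[sim$truth$tf_sign[planted$tf] == -1, ]
  expect_gte(mean(act$rs > 0), 0.9)
  expect_gte(mean(repr$rs < 0), 0.9)
  # sign(RS) always matches sign(rho_TF); p_motif = 1 forces RS = 0
  nz <- reg[reg$rs != 0, ]
  expect_true(all(sign(nz$rs) == sign(nz$rho_tf)))
  expect_true(all(reg$rs[reg$p_motif == 1] == 0))

  sets <- tf_target_sets(reg, tau = 0, expr = rna, calls = sim$truth$senescent)
  for (tf in names(sets)) {
    expect_length(intersect(sets[[tf]]$activated, sets[[tf]]$repressed), 0)
  }
  # tau at the maximum empties both sets
  high <- tf_target_sets(reg, tau = max(abs(reg$rs)) + 1)
  expect_true(all(vapply(high, function(e) length(e$activated) + length(e$repressed),
                         integer(1)) == 0))
})

test_that("chromatin-lead estimation is accurate and antisymmetric", {
  sim <- cached_sim("lead_sim", function() {
    generate_multiome(sim_config(n_cell_types = 1, n_donors_per_group = 5,
                                 cells_per_donor = 300, seed = 29))
  })
  rna <- normalize_log(sim$rna)
  pt <- sim$truth$pseudotime[colnames(rna$counts)]
  cpb <- floor(length(pt) / 100)              # 100 bins across the axis
  leads <- vapply(sim$truth$lead_genes, function(g) {
    ds <- Matrix::colSums(sim$atac$counts[sim$truth$planted_peaks[[g]], ])
    dorc_rna_dynamics(ds, expm1(rna$norm[g, ]), pt, cells_per_bin = cpb)$lead_bins
  }, integer(1))
  expect_lte(median(abs(leads - sim$config$pt_lag_bins)), 3)

  g <- sim$truth$lead_genes[1]
  ds <- Matrix::colSums(sim$atac$counts[sim$truth$planted_peaks[[g]], ])
  fwd <- dorc_rna_dynamics(ds, expm1(rna$norm[g, ]), pt, cells_per_bin = cpb)
  rev_ <- dorc_rna_dynamics(expm1(rna$norm[g, ]), ds, pt, cells_per_bin = cpb)
  expect_equal(fwd$lead_bins, -rev_$lead_bins)
  expect_true(fwd$chromatin_lead)

  same <- dorc_rna_dynamics(ds, ds, pt, cells_per_bin = cpb)
  expect_equal(same$lead_bins, 0L)
  expect_true(all(abs(same$bins$D) < 1e-12))
})

test_that("peak annotation classes partition and honour the boundary conventions", {
  tss <- data.frame(chrom = "chr1", start = c(10000L, 60000L), end = c(30000L, 80000L),
                    strand = "+", symbol = c("GENEB", "GENEA"))
  tss <- senatlas:::add_tss(tss)
  peaks <- data.frame(
    peak_id = c("prom", "prom_edge", "body", "inter", "far", "badchr"),
    chrom = c(rep("chr1", 5), "chrUn"),
    start = c(10800L, 12749L, 24750L, 44750L, 47750L, 100L),
    end = c(11300L, 13249L, 25250L, 45250L, 48250L, 600L))
  h3 <- data.frame(chrom = "chr1", start = 48000L, end = 48100L)
  expect_warning(ann <- annotate_peaks(peaks, tss, h3k27ac = h3), "chrUn")
  expect_equal(nrow(ann), 5)
  expect_equal(ann$class[ann$peak_id == "prom"], "promoter")
  # centre at 12,999 = 2,999 bp from the TSS -> still promoter
  expect_equal(ann$class[ann$peak_id == "prom_edge"], "promoter")
  expect_equal(ann$class[ann$peak_id == "body"], "gene_body")
  expect_equal(ann$class[ann$peak_id == "inter"], "intergenic")
  # 1-bp half-open overlap with the H3K27ac interval flags the enhancer
  expect_true(ann$enhancer[ann$peak_id == "far"])
  expect_false(ann$enhancer[ann$peak_id == "inter"])
  expect_true(all(table(ann$class) >= 0) && sum(table(ann$class)) == nrow(ann))

  tg <- assign_targets(ann, tss, max_dist = 100000)
  expect_true(all(c("GENEB") %in% tg$targets))
  # the enhancer peak is assigned its nearest TSS
  expect_equal(tg$per_peak$target[tg$per_peak$peak_id == "far"], "GENEA")
  # equidistant tie resolves to the lexicographically smaller symbol
  tie_tss <- senatlas:::add_tss(data.frame(chrom = "chr1", start = c(0L, 20000L),
                                           end = c(5000L, 25000L), strand = "+",
                                           symbol = c("ZZZ", "AAA")))
  tie_peak <- data.frame(peak_id = "mid", chrom = "chr1", start = 9750L, end = 10250L)
  ann_tie <- annotate_peaks(tie_peak, tie_tss)
  expect_equal(ann_tie$nearest_gene, "AAA")
})

test_that("planted enhancer-target maps are recovered through annotation", {
  sim <- sim_single_type()
  # the generator's peaks sit within 48 kb of their own TSS and genes are
  # 200 kb apart, so the true target of every peak is its own gene
  pk <- sim$atac$peaks
  ann <- annotate_peaks(pk, sim$tss, h3k27ac = pk[, c("chrom", "start", "end")])
  tg <- assign_targets(ann, sim$tss, max_dist = 100000)
  assigned <- !is.na(tg$per_peak$target)
  expect_gt(sum(assigned), 0.9 * nrow(pk))
  truth_target <- sub("^peak_(.*)_[0-9]+$", "\\1", tg$per_peak$peak_id[assigned])
  expect_gte(mean(tg$per_peak$target[assigned] == truth_target), 0.95)
})
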