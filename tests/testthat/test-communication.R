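test_that("trimean uses linear-interpolation quartiles", {
  sc <- senatlas:::trimean
  expect_equal(sc(c(0, 0, 0, 10)), 1.25)
  expect_equal(sc(rep(7.3, 9)), 7.3)
  expect_equal(sc(rep(0, 5)), 0)
})

test_that("the Hill probability has its closed forms and monotonicity", {
  expect_equal(lr_probability(0, 5), 0)
  expect_equal(lr_probability(1, 1, Kh = 0.5), 2 / 3)
  expect_error(lr_probability(-1, 1), "non-negative")
  x <- seq(0.1, 50, length.out = 40)
  p <- lr_probability(x, 1)
  expect_true(all(diff(p) > 0))
  expect_true(all(p < 1))
  expect_gt(lr_probability(1e9, 1), 0.999)
  # multi-subunit collapse by geometric mean
  expect_equal(lr_probability(c(4, 1), 1, Kh = 0.5), 2 / (0.5 + 2))
})

test_that("permutation p-values are exchangeable-null calibrated and planted pairs extreme", {
  sim <- cached_sim("commune", function() {
    generate_multiome(sim_config(n_genes = 800, n_donors_per_group = 3,
                                 cells_per_donor = 100, seed = 13))
  })
  rna <- norm_rna(sim)
  lrt <- generate_lr_table(sim$config, sim$truth, n_decoys = 60)
  tens <- permutation_significance(rna, lrt, n_perm = 50, seed = 14)
  expect_true(all(tens$p > 0 & tens$p <= 1))
  expect_true(all(tens$prob >= 0 & tens$prob < 1))

  pl <- sim$truth$lr_planted
  hit <- merge(tens, pl, by = "pair_id")
  planted_rows <- hit[hit$sender.x == hit$sender.y & hit$receiver.x == hit$receiver.y, ]
  expect_true(all(planted_rows$p == 1 / 51))

  dec <- tens[grepl("DECOY", tens$pair_id) & tens$sender == "MuSC" & tens$receiver == "FAP", ]
  expect_gt(suppressWarnings(ks.test(dec$p, "punif"))$p.value, 0.01)

  # determinism under the seed
  tens2 <- permutation_significance(rna, lrt, n_perm = 50, seed = 14)
  expect_identical(tens$p, tens2$p)
})

test_that("an absent ligand forces probability 0 and p = 1", {
  X <- matrix(rpois(5 * 30, 5), 5, dimnames = list(c("L0", "R1", "g1", "g2", "g3"),
                                                   sprintf("c%02d", 1:30)))
  X["L0", ] <- 0L
  em <- normalize_log(ExpressionMatrix(X, data.frame(cell_id = colnames(X),
                                                     cell_type = rep(c("A", "B"), 15))))
  lr <- data.frame(pair_id = "p1", pathway = "w")
  lr$ligand <- list("L0"); lr$receptor <- list("R1")
  tens <- permutation_significance(em, lr, n_perm = 20, seed = 1)
  expect_true(all(tens$prob == 0))
  expect_true(all(tens$p == 1))
})

test_that("interaction strength aggregates obey their identities", {
  sim <- cached_sim("commune", function() {
    generate_multiome(sim_config(n_genes = 800, n_donors_per_group = 3,
                                 cells_per_donor = 100, seed = 13))
  })
  rna <- norm_rna(sim)
  lrt <- generate_lr_table(sim$config, sim$truth, n_decoys = 10)
  young <- subset_cells(rna, rna$cells$cell_id[rna$cells$age_group == "young"])
  aged <- subset_cells(rna, rna$cells$cell_id[rna$cells$age_group == "aged"])
  ty <- permutation_significance(young, lrt, n_perm = 50, seed = 15, group = "young")
  ta <- permutation_significance(aged, lrt, n_perm = 50, seed = 16, group = "aged")

  res <- interaction_strength(ta, ty)
  expect_equal(res$total, sum(res$matrix))
  expect_equal(res$total, sum(res$flow))
  rf <- res$relative_flow
  ok <- !is.na(rf[, 1])
  expect_true(all(abs(rowSums(rf[ok, , drop = FALSE]) - 1) < 1e-12))

  # monotone in the significance cut
  t1 <- interaction_strength(ta, p_cut = 0.02)$total
  t2 <- interaction_strength(ta, p_cut = 0.10)$total
  expect_lte(t1, t2)

  # restricting the pair universe never increases aggregates
  sub <- ta[ta$pathway %in% c("SASP-CXCL", "SASP-MMP"), ]
  expect_lte(interaction_strength(sub)$total, interaction_strength(ta)$total)

  # empty significant set
  none <- ta; none$p <- 1
  expect_equal(interaction_strength(none)$total, 0)

  # mismatched pair universes are rejected
  expect_error(interaction_strength(ta, ty[ty$pair_id == ty$pair_id[1], ]), "universe")
})

test_that("renaming cell types permutes the tensor axes identically", {
  set.seed(17)
  X <- matrix(rpois(4 * 40, 4), 4, dimnames = list(c("L1", "R1", "L2", "R2"),
                                                   sprintf("c%02d", 1:40)))
  meta <- data.frame(cell_id = colnames(X), cell_type = rep(c("A", "B"), 20))
  em <- normalize_log(ExpressionMatrix(X, meta))
  lr <- data.frame(pair_id = c("p1", "p2"), pathway = "w")
  lr$ligand <- list("L1", "L2"); lr$receptor <- list("R1", "R2")
  t1 <- permutation_significance(em, lr, n_perm = 20, seed = 2)

  meta2 <- meta; meta2$cell_type <- ifelse(meta$cell_type == "A", "B", "A")
  em2 <- normalize_log(ExpressionMatrix(X, meta2))
  t2 <- permutation_significance(em2, lr, n_perm = 20, seed = 2)
  remap <- function(x) ifelse(x == "A", "B", "A")
  key1 <- paste(t1$sender, t1$receiver, t1$pair_id)
  key2 <- paste(remap(t2$sender), remap(t2$receiver), t2$pair_id)
  expect_equal(t1$prob, t2$prob[match(key1, key2)])
})
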