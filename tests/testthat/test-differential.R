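test_that("rank-sum p is exact for fully separated small groups", {
  X <- matrix(c(1:5, 6:10), nrow = 1,
              dimnames = list("g", sprintf("c%02d", 1:10)))
  de <- rank_sum_de(X, labels = rep(c(TRUE, FALSE), each = 5))
  expect_equal(de$p, 2 / 252, tolerance = 1e-12)

  same <- matrix(rep(c(1, 2, 3), 4)[1:10], nrow = 1,
                 dimnames = list("g", sprintf("c%02d", 1:10)))
  same[1, ] <- 7
  de2 <- rank_sum_de(same, labels = rep(c(TRUE, FALSE), each = 5))
  expect_equal(de2$p, 1)
  expect_equal(de2$log2fc, 0)
})

test_that("exact and normal-approximation branches agree closely at 10 vs 10", {
  set.seed(6)
  for (rep_i in 1:20) {
    x <- matrix(rnorm(20), nrow = 1, dimnames = list("g", sprintf("c%02d", 1:20)))
    lab <- rep(c(TRUE, FALSE), each = 10)
    p_exact <- rank_sum_de(x, lab, exact_max = 10)$p
    p_approx <- rank_sum_de(x, lab, exact_max = 0)$p
    expect_lt(abs(p_exact - p_approx), 0.01)
  }
})

test_that("BH adjustment equals an independent step-up implementation", {
  set.seed(7)
  p <- runif(200)^2
  bh_independent <- function(p) {
    n <- length(p); o <- order(p, decreasing = TRUE)
    ro <- order(o)
    pmin(1, cummin(n / (n:1) * p[o]))[ro]
  }
  X <- matrix(rnorm(200 * 12), 200, dimnames = list(sprintf("g%03d", 1:200), NULL))
  colnames(X) <- sprintf("c%02d", 1:12)
  de <- rank_sum_de(X, rep(c(TRUE, FALSE), 6))
  expect_equal(de$q, bh_independent(de$p), tolerance = 1e-12)
  expect_true(all(de$q >= de$p))
})

test_that("planted senescence program is detected with controlled false positives", {
  sim <- cached_sim("de_scale", function() {
    generate_multiome(sim_config(n_cell_types = 1, n_donors_per_group = 5,
                                 cells_per_donor = 200,
                                 sn_fraction = c(young = 0.2, aged = 0.2), seed = 8))
  })
  rna <- norm_rna(sim)
  sn <- sim$truth$senescent[rna$cells$cell_id]
  de <- rank_sum_de(rna, sn)
  pl <- match(intersect(sim$truth$sn_program, de$gene), de$gene)
  expect_gte(mean(de$log2fc[pl] > 0.5 & de$q[pl] < 0.05), 0.9)
  null_idx <- grep("^FIL-|^INV-|^TRD-|^CCG-", de$gene)
  expect_lte(mean(abs(de$log2fc[null_idx]) > 0.5 & de$q[null_idx] < 0.05), 0.05)
})

test_that("DEG catalogue sharing counts satisfy the partition identities", {
  sim <- sim_default_small()
  rna <- norm_rna(sim)
  call <- uss_classify(score_all(rna, sim$gene_sets), rna$cells$cell_type)
  de_list <- list()
  for (ct in unique(rna$cells$cell_type)) {
    sel <- rna$cells$cell_type == ct
    de_list[[ct]] <- rank_sum_de(subset_cells(rna, rna$cells$cell_id[sel]),
                                 call$senescent[sel])
  }
  cat_ <- sn_deg_catalog(de_list)
  expect_equal(cat_$shared_at_least$up[1], length(cat_$up_union))
  expect_true(all(diff(cat_$shared_at_least$up) <= 0))
  expect_true(all(diff(cat_$shared_at_least$down) <= 0))

  sasp <- intersect_sasp(cat_, sim$gene_sets$sets$SASP)
  expect_equal(sum(sasp$shared_exactly), sasp$union_size)
  expect_true(all(diff(sasp$shared_at_least) <= 0))
  # the globally planted SASP program lands in the shared-in-all-types cell
  expect_gt(sasp$shared_at_least[length(de_list)], 0)

  empty <- intersect_sasp(cat_, c("NOT-A-GENE"))
  expect_equal(empty$union_size, 0)
  disjoint <- sn_deg_catalog(list(a = de_list[[1]][0, ], b = de_list[[2]][0, ]))
  expect_equal(disjoint$shared_at_least$up[2], 0)
})

test_that("hypergeometric enrichment has its closed forms and guards", {
  universe <- sprintf("u%02d", 1:10)
  res <- hypergeom_enrich(universe[1:5], universe, list(hit = universe[1:5]))
  expect_equal(res$p, 1 / 252, tolerance = 1e-12)

  res0 <- hypergeom_enrich(universe[6:10], universe, list(hit = universe[1:5]))
  expect_equal(res0$p, 1)                      # k = 0 -> P[X >= 0] = 1
  resU <- hypergeom_enrich(universe[1:5], universe, list(all = universe))
  expect_equal(resU$p, 1)                      # set = universe
  expect_error(hypergeom_enrich(c("zzz"), universe, list(hit = universe[1:5])),
               "subset")
})
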