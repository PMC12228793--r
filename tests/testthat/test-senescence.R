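test_that("sset_score matches the running-sum oracle on exhaustive toy rankings", {
  # all permutations of 6 distinct expression values, several sets and weights
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
    out
  }
  vals <- c(0.3, 1.1, 2.5, 4.0, 5.2, 9.9)
  for (expr in perms(vals)[seq(1, 720, by = 31)]) {
    for (set_idx in list(1L, c(2L, 5L), c(1L, 3L, 6L))) {
      for (alpha in c(0, 0.25, 1)) {
        expect_equal(sset_score(expr, set_idx, alpha),
                     oracle_sset(expr, set_idx, alpha), tolerance = 1e-12)
      }
    }
  }
  # tied expression values agree with the oracle too
  tied <- c(1, 2, 2, 2, 5, 7)
  expect_equal(sset_score(tied, c(2L, 4L), 0.25), oracle_sset(tied, c(2L, 4L), 0.25),
               tolerance = 1e-12)
})

test_that("extreme singleton sets give the known closed-form scores", {
  expr <- c(a = 4, b = 3, c = 2, d = 1)
  expect_equal(sset_score(expr, "a", alpha = 0), 2.0)   # top-ranked singleton
  expect_equal(sset_score(expr, "d", alpha = 0), -2.0)  # bottom-ranked singleton
  expect_error(sset_score(expr, character(0)), "non-empty")
  expect_error(sset_score(expr, c("a", "b", "c", "d")), "smaller")
})

test_that("scores are invariant to strictly increasing transforms", {
  set.seed(1)
  expr <- rlnorm(50)
  idx <- c(3L, 17L, 40L)
  s0 <- sset_score(expr, idx, 0.25)
  expect_equal(sset_score(exp(expr), idx, 0.25), s0, tolerance = 1e-12)
  expect_equal(sset_score(rank(expr), idx, 0.25), s0, tolerance = 1e-12)
})

test_that("score_all removes exclusions, errors on unmeasurable sets, and is row-consistent", {
  sim <- sim_default_small()
  rna <- norm_rna(sim)
  st <- score_all(rna, sim$gene_sets)
  expect_equal(colnames(st$scores), names(sim$gene_sets$sets))
  # the held-out canonical markers must not contribute to any set
  expect_equal(unname(st$set_sizes["SenMayo"]), 25L)

  ghost <- GeneSetCollection(list(Ghost = c("NOPE1", "NOPE2")))
  expect_error(score_all(rna, ghost), "Ghost")

  # two cells with identical expression get identical score rows
  X <- rna$counts[, c(1, 1)]
  colnames(X) <- c("t1", "t2")
  em <- normalize_log(ExpressionMatrix(X, data.frame(cell_id = c("t1", "t2"))))
  st2 <- score_all(em, sim$gene_sets)
  expect_equal(st2$scores["t1", ], st2$scores["t2", ])
})

test_that("planted senescent cells score higher on every senescence set", {
  sim <- sim_default_small()
  rna <- norm_rna(sim)
  st <- score_all(rna, sim$gene_sets)
  sn <- sim$truth$senescent[rownames(st$scores)]
  for (s in c("SenMayo", "CellAge", "GenAge", "SenescenceEigengene")) {
    expect_gt(mean(st$scores[sn, s]), mean(st$scores[!sn, s]))
  }
})

test_that("the median split is exact for two cells and respects the upper-half cap", {
  S <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8), nrow = 2,
              dimnames = list(c("c1", "c2"),
                              c("SenMayo", "CellAge", "GenAge", "SenescenceEigengene")))
  call <- uss_classify(S, cell_types = c("T", "T"))
  expect_equal(sum(call$senescent), 1)
  expect_true(call$senescent[["c2"]])

  set.seed(2)
  n <- 401  # odd: strictly-above-median count is at most floor(n/2)
  S2 <- matrix(rnorm(n * 4), n,
               dimnames = list(NULL, colnames(S)))
  call2 <- uss_classify(S2, rep("T", n))
  expect_true(all(colSums(call2$indicators) <= ceiling(n / 2)))
})

test_that("senescence calls are invariant to per-set monotone score transforms", {
  set.seed(3)
  n <- 300
  S <- matrix(rnorm(n * 4), n,
              dimnames = list(sprintf("c%03d", 1:n),
                              c("SenMayo", "CellAge", "GenAge", "SenescenceEigengene")))
  types <- rep(c("A", "B"), length.out = n)
  base <- uss_classify(S, types)
  transforms <- list(function(x) exp(x), function(x) x^3, function(x) atan(x) * 5 + 2)
  for (i in 1:3) {
    S2 <- S
    for (j in 1:4) S2[, j] <- transforms[[(i + j) %% 3 + 1]](S[, j])
    expect_identical(uss_classify(S2, types)$senescent, base$senescent)
  }
})

test_that("independent score columns yield the (1/2)^4 null senescent fraction", {
  set.seed(4)
  n <- 20000
  S <- matrix(rnorm(n * 4), n,
              dimnames = list(NULL, c("SenMayo", "CellAge", "GenAge", "SenescenceEigengene")))
  call <- uss_classify(S, rep("T", n))
  p <- 1 / 16
  expect_lt(abs(mean(call$senescent) - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("sn_fraction_table partitions strata and complements sum to 100%", {
  sim <- sim_default_small()
  rna <- norm_rna(sim)
  call <- uss_classify(score_all(rna, sim$gene_sets), rna$cells$cell_type)
  tab <- sn_fraction_table(call, rna$cells)
  expect_equal(sum(tab$n_cells), ncol(rna$counts))
  expect_equal(tab$pct_senescent, 100 * tab$n_senescent / tab$n_cells)
  # young + aged cells of a type sum to the type total
  tot <- tapply(tab$n_cells, tab$cell_type, sum)
  expect_equal(unname(tot[levels(factor(rna$cells$cell_type))[1]]),
               sum(rna$cells$cell_type == levels(factor(rna$cells$cell_type))[1]))
})
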