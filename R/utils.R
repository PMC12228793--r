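# internal helpers shared across modules

# evaluate code under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# column ranks (ascending, average ties) of a genes x cells matrix; dense result
col_ranks <- function(m) {
  m <- as.matrix(m)
  apply(m, 2, rank, ties.method = "average")
}

# row-wise Spearman: standardize row ranks of `m` (p x n), return z-scored
# rank matrix suitable for crossprod-based correlation. Rows with zero
# variance come back as all-NA.
row_rank_z <- function(m) {
  m <- as.matrix(m)
  r <- t(apply(m, 1, rank, ties.method = "average"))
  mu <- rowMeans(r)
  s <- sqrt(pmax(rowSums((r - mu)^2), 0))
  z <- (r - mu) / s
  z[s == 0, ] <- NA_real_
  z
}

# Spearman correlations between all rows of a (via row_rank_z) and one vector
spearman_rows <- function(z_rows, v) {
  rv <- rank(v, ties.method = "average")
  s <- sqrt(sum((rv - mean(rv))^2))
  if (s == 0) return(rep(NA_real_, nrow(z_rows)))
  as.numeric(z_rows %*% ((rv - mean(rv)) / s))
}

# Tukey trimean with linear-interpolation quartiles
trimean <- function(x) {
  q <- stats::quantile(x, probs = c(0.25, 0.5, 0.75), type = 5, names = FALSE)
  (q[1] + 2 * q[2] + q[3]) / 4
}

# nearest-neighbour pools in standardized (gc, mean accessibility) space:
# for each query index, the `k` nearest other peaks (excluding itself)
matched_peak_pool <- function(gc, mean_acc, query_idx, k = 100L) {
  zs <- function(v) {
    s <- stats::sd(v)
    if (is.na(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }
  g <- zs(gc); a <- zs(mean_acc)
  lapply(query_idx, function(i) {
    d2 <- (g - g[i])^2 + (a - a[i])^2
    d2[i] <- Inf
    ord <- order(d2)
    ord[seq_len(min(k, length(ord) - 1L))]
  })
}
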