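# shared lazily-built simulations, generated once per test run

.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(name, builder) {
  if (!exists(name, envir = .sim_cache)) assign(name, builder(), envir = .sim_cache)
  get(name, envir = .sim_cache)
}

# small 4-type multiome used across modules
sim_default_small <- function() cached_sim("default_small", function() {
  generate_multiome(sim_config(n_donors_per_group = 3, cells_per_donor = 120,
                               n_genes = 400, seed = 11))
})

# single-type simulation for trajectory / DORC / regulation work
sim_single_type <- function() cached_sim("single_type", function() {
  generate_multiome(sim_config(n_cell_types = 1, n_donors_per_group = 5,
                               cells_per_donor = 100, seed = 7))
})

norm_rna <- function(sim) normalize_log(sim$rna)

# independent running-sum enrichment oracle: walks the descending ranking
# position by position exactly as the statistic is defined
oracle_sset <- function(expr, set_idx, alpha) {
  n <- length(expr)
  pos <- rank(-expr, ties.method = "average")
  r <- n - pos + 1
  ord <- order(pos)
  inset <- logical(n); inset[set_idx] <- TRUE
  W <- sum(r[inset]^alpha)
  run <- 0; p_in <- 0; p_out <- 0
  for (i in ord) {
    if (inset[i]) p_in <- p_in + r[i]^alpha / W
    else p_out <- p_out + 1 / (n - sum(inset))
    run <- run + (p_in - p_out)
  }
  run
}

# fourth central moment of NB(mu, size) by direct pmf summation
nb_central_moment4 <- function(mu, size) {
  kmax <- qnbinom(1 - 1e-13, mu = mu, size = size)
  k <- 0:kmax
  sum((k - mu)^4 * dnbinom(k, mu = mu, size = size))
}
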