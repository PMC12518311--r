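# Independent brute-force oracles and small fixture builders shared across
# the suite. The oracles deliberately avoid the package's closed forms:
# every exponential sum and window count is evaluated term by term.

# RIE by explicit summation: weighted active recovery over its expectation
# under uniform ranking, both as literal sums over the list.
oracle_rie <- function(active_ranks, N, alpha) {
  n <- length(active_ranks)
  num <- sum(exp(-alpha * active_ranks / N))
  expect_uniform <- (n / N) * sum(exp(-alpha * seq_len(N) / N))
  num / expect_uniform
}

# BEDROC from attained extremes: the best (top-ranks) and worst
# (bottom-ranks) orderings evaluated with the same summation oracle.
oracle_bedroc <- function(active_ranks, N, alpha) {
  n <- length(active_ranks)
  r <- oracle_rie(active_ranks, N, alpha)
  r_top <- oracle_rie(seq_len(n), N, alpha)
  r_bot <- oracle_rie((N - n + 1L):N, N, alpha)
  (r - r_bot) / (r_top - r_bot)
}

oracle_ef <- function(active_ranks, N, chi) {
  w <- max(1L, floor(chi * N))
  sum(active_ranks <= w) / (chi * length(active_ranks))
}

# A tie-free ranked screen whose actives sit exactly at the given ranks.
screen_from_ranks <- function(active_ranks, N) {
  labels <- integer(N)
  labels[active_ranks] <- 1L
  ranked_screen(scores = as.numeric(N - seq_len(N)), labels = labels)
}

# Small planted-signal dataset used by several model-level tests.
small_planted_dataset <- function(seed, n_per_class = 80, effect = 0.8,
                                  flip = 0.02) {
  sim <- simulate_fingerprint_dataset(n_per_class, n_per_class,
                                      effect = effect,
                                      noise_flip_rate = flip, seed = seed)
  list(sim = sim,
       dataset = build_dataset(sim$bits, sim$labels, cell_line = "SYN",
                               seed = seed))
}

# Cell-line model setup (one dataset + the four model families) for
# combination-search tests; quality controlled via the planted effect.
cell_line_setup <- function(cell_line, seed, n_per_class = 60,
                            pool_size = 6) {
  sim <- simulate_fingerprint_dataset(n_per_class, n_per_class, seed = seed)
  ds <- build_dataset(sim$bits, sim$labels, cell_line = cell_line,
                      seed = seed)
  pool <- build_model_pool(ds, target_size = pool_size, seed = seed)
  er <- optimize_ensembles(pool, ds, init_population = 15, generations = 8,
                           max_size = 4, seed = seed)
  list(
    models = list(
      RF = train_model(model_spec("RF", 1:8, seed = seed), ds),
      DTREE = train_model(model_spec("DTREE", 1:8, seed = seed), ds),
      KNN = train_model(model_spec("KNN", 1:8, seed = seed), ds),
      E = ensemble_model(er$ensembles[[1]]$member_ids, pool)
    ),
    dataset = ds
  )
}
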