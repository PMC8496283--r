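# Shared simulation products for the expensive (acceptance-scale) tests.
# Everything is memoised in one environment so several test files can use
# the same replicates without re-simulating; simulations run in batches so
# raw haplotype matrices are never all held in memory at once.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache)) {
    assign(key, force(expr), envir = .sim_cache)
  }
  get(key, envir = .sim_cache)
}

# Per-replicate statistics for `n_reps` replicates of `demography`,
# simulated and processed in batches; replicate ids are made unique across
# batches so aggregation pairs rows correctly.
batched_stats <- function(demography, n_reps, seed,
                          schemes = c("single_population", "merged_panel",
                                      "independent_panel"),
                          thresholds = 0.1,
                          design = sampling_design(),
                          params = sim_params(),
                          batch = 250) {
  n_batches <- ceiling(n_reps / batch)
  purrr::map_dfr(seq_len(n_batches), function(b) {
    n_b <- min(batch, n_reps - (b - 1) * batch)
    reps <- simulate_replicates(demography, n_b, design, params,
                                seed = seed + b)
    stat_seeds <- replicate_seeds(seed + 10000 + b, n_b)
    out <- purrr::map2_dfr(reps, stat_seeds, function(ds, s) {
      replicate_stats(ds, schemes = schemes, thresholds = thresholds,
                      seed = s)
    })
    out$replicate_id <- out$replicate_id + (b - 1) * batch
    out
  })
}

# Per-replicate re-sequencing FST only (typing haplotypes, all sites).
batched_reseq_fst <- function(demography, n_reps, seed,
                              design = sampling_design(),
                              params = sim_params(),
                              batch = 250) {
  n_batches <- ceiling(n_reps / batch)
  unlist(purrr::map(seq_len(n_batches), function(b) {
    n_b <- min(batch, n_reps - (b - 1) * batch)
    reps <- simulate_replicates(demography, n_b, design, params,
                                seed = seed + b)
    vapply(reps, function(ds) fst_hudson(ds, 1, 2, role = "typing"),
           numeric(1))
  }))
}

# --- named products (seeds fixed once) -------------------------------------

two_island_01_stats <- function() {
  cached("two_island_01_stats", batched_stats(
    island_model(2, 0.1), n_reps = 1000, seed = 101,
    thresholds = c(0, 0.025, 0.05, 0.1)))
}

three_island_stats <- function() {
  cached("three_island_stats", batched_stats(
    island_model(3, 0.3), n_reps = 400, seed = 201))
}

stepping_stone_stats <- function() {
  cached("stepping_stone_stats", batched_stats(
    stepping_stone_model(3, 0.3), n_reps = 400, seed = 301))
}

split_model_stats <- function() {
  cached("split_model_stats", batched_stats(
    split_model(), n_reps = 400, seed = 401))
}

three_island_pca_reps <- function() {
  cached("three_island_pca_reps",
         simulate_replicates(island_model(3, 0.3), n_replicates = 100,
                             seed = 211))
}

# Small three-population replicate for cheap structural tests.
small_three_pop_reps <- function() {
  cached("small_three_pop_reps",
         simulate_replicates(island_model(3, 0.3), n_replicates = 3,
                             design = sampling_design(10, 10), seed = 42))
}
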