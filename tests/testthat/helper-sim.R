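# A small, fast simulation design shared across test files (memoized, one
# build per test run).
small_design <- function(seed = 5) {
  simulation_design(
    n_pools = 2L, taxa_per_pool = c(8L, 7L),
    shared_pairs = data.frame(pool_a = 1L, pool_b = 2L, n_shared = 3L),
    n_circular_per_pool = 1L, n_contaminants = 1L, n_broad_taxa = 1L,
    genome_len_range = c(1500L, 2000L), rng_seed = seed)
}

.sim_cache <- new.env()

get_small_sim <- function() {
  if (is.null(.sim_cache$sim)) {
    .sim_cache$sim <- suppressMessages(simulate_pools(small_design()))
  }
  .sim_cache$sim
}

get_small_pools <- function() {
  if (is.null(.sim_cache$pools)) {
    .sim_cache$pools <- suppressMessages(
      annotate_simulation(get_small_sim()))
  }
  .sim_cache$pools
}
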