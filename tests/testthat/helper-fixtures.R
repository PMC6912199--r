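# Shared builders for small in-code fixtures.

# Tiny two-block bundle: quick enough for end-to-end unit tests.
tiny_bundle <- function(seed = 3L) {
  simulate_bilayer(fixture_spec(n_diseases = 10L, n_mirnas = 16L,
                                n_genes = 40L, n_blocks = 2L,
                                target_pool_size = 40L, seed = seed))
}

# Reduced-size model settings so end-to-end unit tests stay fast; the
# acceptance suite exercises the full defaults.
fast_control <- function(seed = 1L, ...) {
  stim_control(
    walk = walk_config(walks_per_node = 5L, walk_length = 20L, dim = 16L,
                       epochs = 3L),
    autoencoder = autoencoder_spec(epochs = 30L),
    forest = deep_forest_config(trees_per_forest = 30L, scan_trees = 10L,
                                max_layers = 1L),
    seed = seed, ...)
}

# Dense labelled similarity matrix with reproducible entries.
toy_similarity <- function(ids, seed = 1L) {
  set.seed(seed)
  m <- matrix(runif(length(ids)^2), length(ids))
  m <- (m + t(m)) / 2
  dimnames(m) <- list(ids, ids)
  m
}

# Complete bipartite association network.
complete_net <- function(diseases, mirnas) {
  association_network(expand.grid(disease = diseases, mirna = mirnas,
                                  stringsAsFactors = FALSE))
}
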