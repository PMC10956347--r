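# one shared small fixture bundle per test session (generation is seeded,
# so sharing is safe); small sizes keep permutation tests quick
small_spec <- function(seed = 11L, ...) {
  fixture_spec(seed = seed, n_genes = 150L, n_cell_types = 3L,
               n_cells_per_type = 20L, module_size = 12L, n_drugs = 24L,
               n_ligands = 12L, min_bin = 15L, ...)
}

.fixture_cache <- new.env(parent = emptyenv())

small_fixture <- function() {
  if (is.null(.fixture_cache$bundle)) {
    .fixture_cache$bundle <- generate_fixture(small_spec())
  }
  .fixture_cache$bundle
}
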