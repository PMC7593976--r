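# Shared world fixtures, built once per test run.

.world_cache <- new.env(parent = emptyenv())

# the default study conditions (40 genomes)
default_world <- function(seed = 1) {
  key <- paste0("default_", seed)
  if (is.null(.world_cache[[key]]))
    .world_cache[[key]] <- build_world(world_config(seed = seed))
  .world_cache[[key]]
}

# a small world for unit tests of downstream modules
small_world <- function(seed = 3) {
  key <- paste0("small_", seed)
  if (is.null(.world_cache[[key]]))
    .world_cache[[key]] <- build_world(world_config(
      n_genomes = 10, n_clades = 2, n_subfamilies = 2,
      neighborhood_bias = c(CL1 = "M", CL2 = "G"),
      paralog_presence = 0.6, unknown_genomes = 2, n_hgt_events = 1,
      n_duplications = 1, n_reduced_genomes = 1, decoys_per_genome = 12,
      seed = seed))
  .world_cache[[key]]
}

# genes of a world as a data frame with a convenience truth vector
world_truth_map <- function(world) {
  g <- world_genes(world)
  setNames(g$truth_family, g$gene_id)
}
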