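# Synthetic world generator: determinism, planted structure, and the
# conserved-operon invariant.

test_that("species tree sampling is deterministic and well-formed", {
  t1 <- sample_species_tree(8, seed = 7)
  t2 <- sample_species_tree(8, seed = 7)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  t3 <- sample_species_tree(3, seed = 1)
  expect_equal(length(t3$tip.label), 3)
  expect_equal(t3$Nnode, 2)   # rooted 3-leaf tree: one internal split
  t50 <- sample_species_tree(50, seed = 2)
  expect_gt(sum(t50$edge.length), 0)
  expect_equal(anyDuplicated(t50$tip.label), 0)
  expect_error(sample_species_tree(2, seed = 1), "at least 3")
})

test_that("family evolution respects rate, constraints and determinism", {
  tr <- sample_species_tree(6, seed = 5)
  anc <- strrep("ACDEFGHIKL", 10)
  tips0 <- evolve_family(anc, tr, rate_multiplier = 0, seed = 2)
  expect_true(all(tips0 == anc))
  tips_c <- evolve_family(anc, tr, 1, site_states = c("10" = "K"), seed = 2)
  expect_true(all(substr(tips_c, 10, 10) == "K"))
  # higher multiplier, same seed and tree: strictly larger mean divergence
  t1 <- evolve_family(anc, tr, 1, seed = 9)
  t3 <- evolve_family(anc, tr, 3, seed = 9)
  expect_gt(mean(vapply(t3, pdist, numeric(1), b = anc)),
            mean(vapply(t1, pdist, numeric(1), b = anc)))
  expect_error(evolve_family(anc, tr, 1, site_states = c("500" = "K")),
               "out of range")
})

test_that("the world is deterministic down to bytes on disk", {
  cfg <- world_config(n_genomes = 8, n_clades = 2, n_subfamilies = 2,
                      neighborhood_bias = c(CL1 = "M", CL2 = "G"),
                      unknown_genomes = 1, n_hgt_events = 1,
                      n_duplications = 0, n_reduced_genomes = 1,
                      decoys_per_genome = 8, seed = 12)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_world(build_world(cfg), d1)
  write_world(build_world(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("reduced genomes lack the housekeeping gene but keep all controls", {
  w <- small_world()
  g <- world_genes(w)
  red <- w$truth$reduced_genomes
  expect_length(red, 1)
  for (gid in names(w$genomes)) {
    fams <- g$truth_family[g$genome_id == gid]
    if (gid %in% red) expect_false("housekeeping" %in% fams)
    else expect_true("housekeeping" %in% fams)
    expect_true(all(rfahkit:::CONTROL_FAMILIES %in% fams))
  }
})

test_that("every non-reduced genome has exactly one conserved operon locus", {
  w <- small_world()
  for (gn in w$genomes) {
    loci <- operon_context(gn, c("control_secE", "housekeeping",
                                 "control_rplK", "control_rplA"),
                           optional_slot = 2)
    expect_equal(nrow(loci), 1, info = gn$genome_id)
    expected <- if (gn$genome_id %in% w$truth$reduced_genomes) "gapped"
                else "intact"
    expect_identical(loci$status, expected, info = gn$genome_id)
  }
})

test_that("truth tables are consistent with the emitted genomes", {
  w <- small_world()
  g <- world_genes(w)
  fm <- w$truth$family_membership
  # every labeled gene occurs exactly once in exactly one genome
  expect_equal(anyDuplicated(fm$gene_id), 0)
  expect_true(all(fm$gene_id %in% g$gene_id))
  idx <- match(fm$gene_id, g$gene_id)
  expect_identical(g$truth_family[idx], fm$family)
  expect_identical(g$genome_id[idx], fm$genome_id)
  # planted clusters and HGT events cover only paralog genes
  pc <- w$truth$planted_clusters
  expect_true(all(pc$gene_id %in% fm$gene_id[fm$family == "paralog"]))
  hg <- w$truth$hgt_events
  expect_equal(nrow(hg), 1)
  expect_true(all(hg$gene_id %in% pc$gene_id))
  # each transferred gene sits in a genome outside its donor clade
  clades <- w$truth$clades
  expect_true(all(clades[hg$recipient_genome] != hg$donor_clade))
  # gene indices are consecutive per contig
  for (gn in w$genomes)
    expect_identical(gn$genes$index, seq_len(nrow(gn$genes)) - 1L)
})

test_that("infeasible configs are rejected", {
  cfg <- world_config(n_genomes = 8, n_clades = 2, n_subfamilies = 2,
                      neighborhood_bias = c(CL1 = "M", CL2 = "G"),
                      paralog_presence = 1, n_hgt_events = 5,
                      n_reduced_genomes = 0, decoys_per_genome = 5, seed = 1)
  expect_error(build_world(cfg), "infeasible")
  expect_error(world_config(n_genomes = 8, n_reduced_genomes = 8), "n_reduced")
})
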