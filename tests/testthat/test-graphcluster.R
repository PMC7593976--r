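# Redundancy reduction, similarity-graph admission rules, and MCL.

make_graph <- function(nodes, edges) {
  structure(list(nodes = nodes, edges = edges), class = "similarity_graph")
}

edge_df <- function(a, b, w) {
  data.frame(node_a = a, node_b = b, evalue_ab = 10^-w, evalue_ba = 10^-w,
             weight = w, stringsAsFactors = FALSE)
}

test_that("greedy redundancy reduction honors identity thresholds", {
  s <- strrep("MKWLVANDERQHGCF", 10)   # 150 residues
  copies <- setNames(rep(s, 4), paste0("c", 1:4))
  r <- reduce_redundancy(copies, 0.95)
  expect_length(r$representatives, 1)
  expect_true(all(r$membership == r$representatives))
  # ~90% identity pair splits at 0.95
  s2 <- strsplit(s, "")[[1]]
  idx <- seq(1, 150, by = 10)
  s2[idx] <- ifelse(s2[idx] == "A", "C", "A")   # 15 changes = 10%
  two <- c(a = s, b = paste(s2, collapse = ""))
  expect_length(reduce_redundancy(two, 0.95)$representatives, 2)
  expect_length(reduce_redundancy(two, 0.85)$representatives, 1)
  # threshold 1.0 keeps only exact duplicates together
  r3 <- reduce_redundancy(c(copies, two["b"]), 1.0)
  expect_length(r3$representatives, 2)
  expect_equal(length(reduce_redundancy(character(0), 0.9)$representatives), 0)
})

test_that("graph edges require E-value and coverage in both directions", {
  w <- small_world()
  par <- rfahkit:::family_sequences(w, "paralog")
  cfg <- cluster_config()
  g <- build_similarity_graph(par, cfg)
  expect_setequal(g$nodes, names(par))
  expect_true(all(g$edges$weight > 0))
  # every admitted edge satisfies the cutoffs; weight is the -log10 mean
  expect_true(all(g$edges$evalue_ab <= cfg$evalue_max))
  expect_equal(g$edges$weight,
               -log10(pmax((g$edges$evalue_ab + g$edges$evalue_ba) / 2,
                           cfg$evalue_floor)))
  # no within-pair self edges
  expect_true(all(g$edges$node_a != g$edges$node_b))
  # stricter E-value cutoff never adds edges
  g2 <- build_similarity_graph(par, cluster_config(evalue_max = 1e-60))
  expect_lte(nrow(g2$edges), nrow(g$edges))
  # coverage gate: shuffled decoys share no long alignment, so no edges
  set.seed(1)
  decoys <- setNames(replicate(3, rand_prot(150, rownames(align_params()$matrix))),
                     c("d1", "d2", "d3"))
  g3 <- build_similarity_graph(decoys, cfg)
  expect_equal(nrow(g3$edges), 0)
})

test_that("MCL respects graph components and attractor structure", {
  tri <- rbind(edge_df(c("a", "b", "c"), c("b", "c", "a"), 40),
               edge_df(c("x", "y", "z"), c("y", "z", "x"), 40))
  m <- mcl(make_graph(c("a", "b", "c", "x", "y", "z"), tri))
  expect_true(m$converged)
  expect_length(unique(m$clusters), 2)
  expect_length(unique(m$clusters[c("a", "b", "c")]), 1)
  expect_length(unique(m$clusters[c("x", "y", "z")]), 1)
  # isolated node is a singleton cluster
  m2 <- mcl(make_graph("lonely", edge_df(character(0), character(0), numeric(0))))
  expect_identical(unname(m2$clusters), "CL1")
  # K2 with equal weights collapses to one cluster
  m3 <- mcl(make_graph(c("u", "v"), edge_df("u", "v", 40)))
  expect_length(unique(m3$clusters), 1)
})

test_that("MCL labels are equivariant under node relabeling", {
  e <- rbind(edge_df(c("a", "b", "c"), c("b", "c", "a"), 35),
             edge_df(c("p", "q"), c("q", "p"), 50)[1, ])
  g1 <- make_graph(c("a", "b", "c", "p", "q"), e)
  m1 <- mcl(g1)
  ren <- c(a = "n3", b = "n1", c = "n2", p = "n5", q = "n4")
  e2 <- e
  e2$node_a <- unname(ren[e$node_a]); e2$node_b <- unname(ren[e$node_b])
  m2 <- mcl(make_graph(unname(ren[g1$nodes]), e2))
  # partition is identical up to label names
  canon <- function(cl) {
    sets <- split(names(cl), cl)
    unname(sort(vapply(sets, function(x) paste(sort(x), collapse = ","),
                       character(1))))
  }
  m2_back <- setNames(m2$clusters, names(ren)[match(names(m2$clusters), ren)])
  expect_identical(canon(m1$clusters), canon(m2_back))
})

test_that("stepwise clustering recovers the planted subfamilies", {
  w <- small_world()
  pc <- w$truth$planted_clusters
  g <- world_genes(w)
  seqs <- setNames(g$protein_sequence[match(pc$gene_id, g$gene_id)],
                   pc$gene_id)
  res <- stepwise_cluster(seqs)
  ari <- mclust::adjustedRandIndex(res$clusters[pc$gene_id], pc$cluster)
  expect_gte(ari, 0.95)
  # determinism
  res2 <- stepwise_cluster(seqs)
  expect_identical(res$clusters, res2$clusters)
  # all-identical input collapses to one representative and one cluster
  same <- setNames(rep(seqs[1], 3), c("s1", "s2", "s3"))
  expect_length(unique(stepwise_cluster(same)$clusters), 1)
})

test_that("similarity graphs round-trip through ABC format", {
  w <- small_world()
  par <- rfahkit:::family_sequences(w, "paralog")
  g <- build_similarity_graph(par, cluster_config())
  path <- withr::local_tempfile(fileext = ".abc")
  write_graph_abc(g, path)
  g2 <- read_graph_abc(path, nodes = g$nodes)
  expect_identical(g2$nodes, g$nodes)
  expect_equal(g2$edges$weight, g$edges$weight, tolerance = 1e-5)
  expect_identical(g2$edges$node_a, g$edges$node_a)
})
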