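# Distances, neighbor joining, Robinson-Foulds, tree diameters and the
# concatenated marker tree.

test_that("p-distances and the Poisson correction follow the formulas", {
  msa <- msa_from_stack(c(a = "AAAAAAAAAA", b = "AAAAAAAAAA",
                          c = "AAAAAAAAAC"))
  D <- distance_matrix(msa, "none")
  expect_equal(D["a", "b"], 0)
  expect_equal(D["a", "c"], 0.1)
  Dp <- distance_matrix(msa, "poisson")
  expect_equal(Dp["a", "c"], -log(0.9), tolerance = 1e-12)
  # saturation cap
  msa2 <- msa_from_stack(c(a = "AAAA", b = "CCCC", c = "AACC"))
  Dp2 <- distance_matrix(msa2, "poisson", p_max = 0.95)
  expect_equal(Dp2["a", "b"], -log(0.05), tolerance = 1e-12)
  # pairwise deletion: gap columns are excluded per pair
  msa3 <- structure(list(ids = c("a", "b", "c"),
                         rows = c(a = "A-AA", b = "ACAA", c = "ACAC"),
                         width = 4), class = "msa")
  D3 <- distance_matrix(msa3, "none")
  expect_equal(D3["a", "b"], 0)      # 3 comparable columns, all equal
  expect_equal(D3["a", "c"], 1 / 3)
})

test_that("neighbor joining solves the three-point configuration", {
  D <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(D)
  tip_edge <- setNames(tr$edge.length[match(seq_len(3), tr$edge[, 2])],
                       tr$tip.label)
  expect_equal(tip_edge[["a"]], 1)
  expect_equal(tip_edge[["b"]], 1)
  expect_equal(tip_edge[["c"]], 3)
  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("NJ exactly recovers additive trees (50 random cases)", {
  set.seed(99)
  for (k in 1:50) {
    n <- sample(6:12, 1)
    true <- ape::rtree(n, br = function(x) runif(x, 0.1, 1))
    D <- ape::cophenetic.phylo(true)
    D <- D[order(rownames(D)), order(colnames(D))]
    est <- neighbor_joining(D)
    expect_equal(unname(robinson_foulds(est, true)["raw"]), 0, info = k)
  }
})

test_that("Robinson-Foulds counts split differences as defined", {
  t1 <- ape::read.tree(text = "((a,b),(c,d));")
  expect_equal(unname(robinson_foulds(t1, t1)), c(0, 0))
  t2 <- ape::read.tree(text = "((a,c),(b,d));")
  expect_equal(unname(robinson_foulds(t1, t2)), c(2, 1))
  t3a <- ape::read.tree(text = "(a:1,b:1,c:2);")
  t3b <- ape::read.tree(text = "(b:1,c:3,a:1);")
  expect_equal(unname(robinson_foulds(t3a, t3b)), c(0, 0))
  expect_error(robinson_foulds(t1, t3a), "leaf sets")
})

test_that("the longest path matches a brute-force over leaf pairs", {
  star <- ape::read.tree(text = "(a:1,b:2,c:3);")
  expect_equal(longest_path_sum(star), 5)
  two <- ape::read.tree(text = "(a:2.5,b:1.5);")
  expect_equal(longest_path_sum(two), 4)
  set.seed(21)
  tr <- ape::rtree(20)
  n <- length(tr$tip.label)
  brute <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    # nodepath lists nodes; sum the edges between consecutive nodes
    pth <- ape::nodepath(tr, i, j)
    len <- 0
    for (s in seq_len(length(pth) - 1)) {
      e <- which((tr$edge[, 1] == pth[s] & tr$edge[, 2] == pth[s + 1]) |
                   (tr$edge[, 2] == pth[s] & tr$edge[, 1] == pth[s + 1]))
      len <- len + tr$edge.length[e]
    }
    if (len > brute) brute <- len
  }
  expect_equal(longest_path_sum(tr), brute, tolerance = 1e-9)
  expect_error(longest_path_sum(ape::read.tree(text = "(a:1);")), "2 leaves")
})

test_that("midpoint rooting splits the diameter and is idempotent", {
  two <- ape::read.tree(text = "(a:3,b:1);")
  r <- midpoint_root(two)
  expect_equal(sort(r$edge.length), c(2, 2))
  sym <- ape::read.tree(text = "((a:1,b:1):2,(c:1,d:1):2);")
  r2 <- midpoint_root(sym)
  expect_equal(max(ape::node.depth.edgelength(r2)), 3)
  r3 <- midpoint_root(r2)
  expect_equal(ape::dist.topo(ape::unroot(r3), ape::unroot(r2)), 0,
               ignore_attr = TRUE)
  expect_equal(longest_path_sum(r3), longest_path_sum(r2))
})

test_that("concatenated marker trees recover the species tree", {
  w <- small_world()
  g <- world_genes(w)
  fam <- world_truth_map(w)
  markers <- lapply(rfahkit:::CONTROL_FAMILIES, function(f) {
    sel <- !is.na(g$truth_family) & g$truth_family == f
    setNames(g$protein_sequence[sel], g$genome_id[sel])
  })
  tr <- concat_marker_tree(w, markers)
  expect_equal(unname(robinson_foulds(tr, w$truth$species_tree)["raw"]), 0)
  # a single marker equals that family's tree
  t1 <- concat_marker_tree(w, markers[1])
  t1b <- family_tree(markers[[1]])
  expect_equal(unname(robinson_foulds(t1, t1b)["raw"]), 0)
  # a genome lacking a marker is reported by name
  short <- markers
  short[[1]] <- short[[1]][-1]
  expect_error(concat_marker_tree(w, short), "genome_")
})

test_that("gene-tree congruence separates vertical from transferred families", {
  # a single transfer in a tiny world can be topologically invisible (the
  # recipient attaches as an outgroup of the donor subfamily), so this runs
  # on the default conditions with several planted transfers
  w <- default_world(seed = 1)
  g <- world_genes(w)
  fam <- world_truth_map(w)
  hk <- rfahkit:::family_sequences(w, "housekeeping")
  names(hk) <- g$genome_id[match(names(hk), g$gene_id)]
  hk_tree <- family_tree(hk)
  st <- ape::keep.tip(w$truth$species_tree, names(hk))
  expect_equal(unname(robinson_foulds(hk_tree, st)["raw"]), 0)
  pc <- w$truth$planted_clusters
  native <- pc[!pc$dup & !duplicated(pc$genome_id), ]
  par_tree <- family_tree(setNames(
    g$protein_sequence[match(native$gene_id, g$gene_id)], native$genome_id))
  stp <- ape::keep.tip(w$truth$species_tree, native$genome_id)
  expect_gt(unname(robinson_foulds(par_tree, stp)["raw"]), 0)
})
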