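# Phyletic profiles, per-taxon percentages, the completeness screen and
# operon context reports.

# a synthetic presence matrix exercising the pure tabular operations
toy_matrix <- function() {
  m <- matrix(0L, 12, 3, dimnames = list(paste0("g", 1:12),
                                         c("focal", "ctrl1", "ctrl2")))
  m[, "ctrl1"] <- 1L
  m[, "ctrl2"] <- 1L
  m[1:5, "focal"] <- 1L
  m["g6", "ctrl2"] <- 0L   # incomplete genome: missing a control
  m
}

test_that("percent hits follow the minimum-taxon-size rule", {
  m <- toy_matrix()
  tax <- setNames(c(rep("big", 10), rep("small", 2)), rownames(m))
  pct <- percent_hits(m, tax, "focal", min_genomes = 10)
  expect_equal(unname(pct["big"]), 0.5)
  expect_false("small" %in% names(pct))
  pct2 <- percent_hits(m, tax, "ctrl1", min_genomes = 2)
  expect_equal(unname(pct2), c(1, 1))
})

test_that("completeness screen demands all controls and no focal hit", {
  m <- toy_matrix()
  flagged <- completeness_screen(m, "focal", c("ctrl1", "ctrl2"))
  expect_setequal(flagged, paste0("g", 7:12))   # g6 lacks ctrl2
  expect_false("g6" %in% flagged)
  expect_false("g1" %in% flagged)
  expect_error(completeness_screen(m, "nope", "ctrl1"), "focal")
})

test_that("presence matrix counts member hits per genome and model", {
  w <- small_world()
  g <- world_genes(w)
  fam <- world_truth_map(w)
  models <- lapply(c("housekeeping", rfahkit:::CONTROL_FAMILIES), function(f) {
    ids <- names(fam)[!is.na(fam) & fam == f]
    m <- build_profile(msa_from_stack(
      setNames(g$protein_sequence[match(ids, g$gene_id)], ids)))
    bits <- rfahkit:::score_sequences(m, setNames(g$protein_sequence,
                                                  g$gene_id))
    calibrate_cutoffs(m, bits[ids], bits[is.na(fam)])
  })
  names(models) <- c("housekeeping", rfahkit:::CONTROL_FAMILIES)
  hits <- lapply(models, function(m) scan_proteomes(m, w))
  pm <- presence_matrix(hits, w)
  red <- w$truth$reduced_genomes
  expect_true(all(pm[red, "housekeeping"] == 0))
  expect_true(all(pm[setdiff(rownames(pm), red), "housekeeping"] >= 1))
  expect_true(all(pm[, rfahkit:::CONTROL_FAMILIES] >= 1))
  # the completeness screen flags exactly the planted reduced genomes
  flagged <- completeness_screen(pm, "housekeeping",
                                 rfahkit:::CONTROL_FAMILIES)
  expect_setequal(flagged, red)
  # empty hit table gives an all-zero column
  pm2 <- presence_matrix(c(hits, list(absent = hits[[1]][0, ])), w)
  expect_true(all(pm2[, "absent"] == 0))
  bad <- hits[[1]]
  bad$genome_id <- "not_a_genome"
  expect_error(presence_matrix(list(x = bad), w), "unknown genome")
})

test_that("operon context distinguishes intact, gapped and absent loci", {
  genes <- data.frame(
    gene_id = paste0("t", 1:6), contig_id = "c1", index = 0:5,
    strand = c("+", "+", "+", "+", "-", "+"),
    cog_category = "R",
    truth_family = c(NA, "control_secE", "housekeeping", "control_rplK",
                     "control_rplA", NA),
    protein_sequence = "MKW", stringsAsFactors = FALSE)
  gn <- structure(list(genome_id = "t", lineage = c("x", "x"), genes = genes),
                  class = "genome")
  pattern <- c("control_secE", "housekeeping", "control_rplK", "control_rplA")
  # strand break at rplA: no full-pattern run on one strand
  expect_equal(nrow(operon_context(gn, pattern)), 0)
  genes$strand <- "+"
  gn$genes <- genes
  loci <- operon_context(gn, pattern)
  expect_identical(loci$status, "intact")
  expect_equal(loci$start_index, 1L)
  # dropping the housekeeping gene yields a gapped locus
  genes2 <- genes[-3, ]
  genes2$index <- 0:4
  gn2 <- gn; gn2$genes <- genes2
  expect_identical(operon_context(gn2, pattern)$status, "gapped")
  # no secE at all: no loci
  genes3 <- genes[-2, ]
  genes3$index <- 0:4
  gn3 <- gn; gn3$genes <- genes3
  expect_equal(nrow(operon_context(gn3, pattern)), 0)
})
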