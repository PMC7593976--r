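# Center-star MSA, profile construction, Viterbi scoring against the
# path-enumeration oracle, cutoffs, and the model-building workflow.

test_that("center-star MSA handles identical, stacked and mixed inputs", {
  p <- align_params()
  m1 <- center_star_msa(c(a = "ACDEF", b = "ACDEF", c = "ACDEF"), p)
  expect_equal(m1$width, 5)
  expect_false(any(grepl("-", m1$rows, fixed = TRUE)))
  # equal-length indel-free family: gap-free stack
  w <- small_world()
  hk <- rfahkit:::family_sequences(w, "housekeeping")
  m2 <- center_star_msa(hk[1:4], p)
  expect_equal(m2$width, unique(nchar(hk)))
  expect_false(any(grepl("-", m2$rows, fixed = TRUE)))
  # mixed lengths: every row degaps to its input
  seqs <- c(x = "MKLVWAAG", y = "MKLWAAG", z = "MKLVWAAGGH")
  m3 <- center_star_msa(seqs, p)
  for (id in names(seqs))
    expect_identical(gsub("-", "", m3$rows[[id]]), unname(seqs[id]))
  expect_equal(length(unique(nchar(m3$rows))), 1)
  expect_error(center_star_msa(seqs[1], p), "at least 2")
})

test_that("profile construction follows the stated pseudocount rules", {
  msa <- msa_from_stack(c(s1 = "AAC", s2 = "AAC", s3 = "AAC", s4 = "AAW"))
  m <- build_profile(msa)
  expect_equal(m$n_match_states, 3)
  # column of 4 A's, uniform background: P(A) = (4 + 0.05) / 5
  expect_equal(unname(m$match_emissions[1, "A"]), 0.81)
  expect_equal(unname(m$match_emissions[3, "C"]), 3.05 / 5)
  expect_equal(unname(m$match_emissions[3, "W"]), 1.05 / 5)
  # every emission and transition vector is normalized
  expect_true(all(abs(rowSums(m$match_emissions) - 1) < 1e-9))
  for (j in seq_len(nrow(m$transitions))) {
    tm <- sum(m$transitions[j, c("MM", "MD", "MI")])
    expect_equal(tm, 1, tolerance = 1e-9)
  }
  # a column with >50% gaps is not a match state
  msa2 <- structure(list(ids = c("a", "b", "c", "d", "e"),
                         rows = c(a = "A-C", b = "A-C", c = "A-C",
                                  d = "AWC", e = "AWC"),
                         width = 3), class = "msa")
  m2 <- build_profile(msa2, gap_fraction_max = 0.5)
  expect_equal(m2$n_match_states, 2)
  expect_error(build_profile(msa2, gap_fraction_max = 0.1),
               NA)  # cols 1 and 3 are gap-free, still 2 match states
})

test_that("Viterbi bits equal exhaustive path enumeration on toy models", {
  msa <- msa_from_stack(c(a = "KWND", b = "KWND", c = "KWCD", d = "KFND"))
  model <- build_profile(msa)
  lm <- rfahkit:::model_log_matrices(model)
  set.seed(5)
  for (k in 1:20) {
    n <- sample(1:6, 1)
    x <- sample(0:19, n, replace = TRUE)
    seq <- paste(rfahkit:::AA_ALPHABET[x + 1], collapse = "")
    expect_equal(score_sequence(model, seq),
                 oracle_viterbi(lm$em, lm$tl, x),
                 tolerance = 1e-9, info = seq)
  }
})

test_that("consensus scores positive and dominates the training rows", {
  w <- small_world()
  hk <- rfahkit:::family_sequences(w, "housekeeping")
  model <- build_profile(msa_from_stack(hk))
  cons_bits <- score_sequence(model, model_consensus(model))
  expect_gt(cons_bits, 0)
  row_bits <- rfahkit:::score_sequences(model, hk)
  expect_true(all(cons_bits >= row_bits))
})

test_that("bits are invariant to null-scored flanks", {
  msa <- msa_from_stack(c(a = "KWNDAY", b = "KWNDAY", c = "KWCDAY"))
  model <- build_profile(msa)
  core <- "KWNDAY"
  with_flanks <- paste0("MGS", core, "LLQ")
  expect_equal(score_sequence(model, core),
               score_sequence(model, with_flanks), tolerance = 1e-9)
})

test_that("cutoff calibration follows the Pfam convention", {
  msa <- msa_from_stack(c(a = "KWND", b = "KWND"))
  m <- build_profile(msa)
  m2 <- calibrate_cutoffs(m, c(50.1, 62.3), c(12.0, 30.5))
  expect_equal(m2$trusted_cutoff, 50.1)
  expect_equal(m2$noise_cutoff, 30.5)
  expect_error(calibrate_cutoffs(m, 40, 40), "non-separable")
  m3 <- calibrate_cutoffs(m, 75, 10)
  expect_equal(c(m3$trusted_cutoff, m3$noise_cutoff), c(75, 10))
  expect_error(calibrate_cutoffs(m, numeric(0), 1), "non-empty")
})

test_that("hit classification respects boundary semantics", {
  msa <- msa_from_stack(c(a = "KWND", b = "KWND"))
  m <- calibrate_cutoffs(build_profile(msa), 50, 30)
  expect_identical(classify_hit(c(55, 50, 40, 30, 10), m),
                   c("member", "member", "candidate", "none", "none"))
  expect_error(classify_hit(10, build_profile(msa)), "cutoffs")
})

test_that("proteome scanning finds planted families where they belong", {
  w <- small_world()
  g <- world_genes(w)
  fam <- world_truth_map(w)
  hk_ids <- names(fam)[!is.na(fam) & fam == "housekeeping"]
  model <- build_profile(msa_from_stack(
    setNames(g$protein_sequence[match(hk_ids, g$gene_id)], hk_ids)))
  bits <- rfahkit:::score_sequences(
    model, setNames(g$protein_sequence, g$gene_id))
  model <- calibrate_cutoffs(model, bits[hk_ids],
                             bits[is.na(fam)])   # decoys as negatives
  hits <- scan_proteomes(model, w)
  members <- hits[hits$zone == "member", ]
  red <- w$truth$reduced_genomes
  for (gid in names(w$genomes)) {
    if (gid %in% red)
      expect_false(gid %in% members$genome_id)
    else expect_true(gid %in% members$genome_id)
  }
  # no decoy reaches the member zone
  expect_true(all(!is.na(fam[members$gene_id])))
  expect_equal(nrow(scan_proteomes(model, list())), 0)
})

test_that("the full model-building workflow separates the three zones", {
  w <- small_world()
  g <- world_genes(w)
  fam <- world_truth_map(w)
  par_ids <- names(fam)[!is.na(fam) & fam == "paralog"]
  unk_ids <- names(fam)[!is.na(fam) & fam == "unknown"]
  seqs <- setNames(g$protein_sequence, g$gene_id)
  model <- build_family_model(seqs[par_ids], w,
                              positives_ids = par_ids,
                              negatives_ids = setdiff(g$gene_id,
                                                      c(par_ids, unk_ids)),
                              required_sites = rfahkit:::PARALOG_SITES)
  expect_gt(model$trusted_cutoff, model$noise_cutoff)
  bits <- rfahkit:::score_sequences(model, seqs)
  zone <- classify_hit(bits, model)
  expect_true(all(zone[par_ids] == "member"))
  expect_true(all(zone[unk_ids] == "candidate"))
  expect_error(build_family_model(seqs[par_ids[1:3]], w, par_ids, NULL),
               "at least 5")
})

test_that("profiles and MSAs round-trip through their text formats", {
  w <- small_world()
  hk <- rfahkit:::family_sequences(w, "housekeeping")
  msa <- msa_from_stack(hk)
  mp <- withr::local_tempfile(fileext = ".afa")
  write_msa(msa, mp)
  msa2 <- read_msa(mp)
  expect_identical(unname(msa2$rows), unname(msa$rows))
  model <- calibrate_cutoffs(build_profile(msa), 100, -5)
  pp <- withr::local_tempfile(fileext = ".txt")
  write_profile(model, pp)
  model2 <- read_profile(pp)
  expect_equal(model2$n_match_states, model$n_match_states)
  expect_equal(model2$trusted_cutoff, model$trusted_cutoff)
  expect_equal(model2$noise_cutoff, model$noise_cutoff)
  expect_equal(unname(model2$match_emissions), unname(model$match_emissions),
               tolerance = 1e-8)
  expect_equal(unname(model2$transitions), unname(model$transitions),
               tolerance = 1e-8)
  s <- rfahkit:::family_sequences(w, "paralog")[1]
  expect_equal(score_sequence(model2, s), score_sequence(model, s),
               tolerance = 1e-6)
})
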