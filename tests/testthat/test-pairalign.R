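# Pairwise alignment: worked examples frozen from matrix arithmetic and the
# enumeration oracle, plus oracle-equivalence and symmetry properties.

p <- align_params()
B <- p$matrix

test_that("global alignment reproduces hand-derived scores", {
  expect_equal(global_align("AAG", "AAG", p)$raw_score, 14)  # 4 + 4 + 6
  a <- global_align("AAAA", "AAAT", p)
  expect_equal(a$raw_score, 3 * B["A", "A"] + B["A", "T"])
  expect_equal(nchar(a$aligned_query), 4)        # no gaps
  expect_false(grepl("-", a$aligned_query, fixed = TRUE))
  # one gap of length 4 costs 11 + 4*1
  expect_equal(global_align("ACDE", "", p)$raw_score, -15)
  expect_equal(global_align("", "", p)$raw_score, 0)
})

test_that("local alignment reproduces matrix lookups and the SW floor", {
  expect_equal(local_align("W", "W", p)$raw_score, B["W", "W"])  # 11
  neg <- local_align("A", "D", p)   # no positive pair: A-D scores -2
  expect_equal(neg$raw_score, 0)
  expect_equal(neg$query_span, c(0L, 0L))
  expect_equal(neg$subject_span, c(0L, 0L))
})

test_that("alignment scores equal exhaustive enumeration (4-letter alphabet)", {
  sub <- c("A", "C", "D", "W")
  set.seed(42)
  for (k in 1:25) {
    a <- rand_prot(sample(1:6, 1), sub)
    b <- rand_prot(sample(1:6, 1), sub)
    ia <- match(strsplit(a, "")[[1]], rownames(B))
    ib <- match(strsplit(b, "")[[1]], rownames(B))
    expect_equal(global_align(a, b, p)$raw_score,
                 oracle_global(rownames(B)[ia], rownames(B)[ib], B),
                 info = paste(a, b))
  }
  # a couple of full-length (8 x 8) pairs
  for (k in 1:2) {
    a <- rand_prot(8, sub); b <- rand_prot(8, sub)
    expect_equal(global_align(a, b, p)$raw_score,
                 oracle_global(strsplit(a, "")[[1]], strsplit(b, "")[[1]], B))
  }
  # local oracle on shorter pairs
  for (k in 1:8) {
    a <- rand_prot(sample(2:5, 1), sub)
    b <- rand_prot(sample(2:5, 1), sub)
    expect_equal(local_align(a, b, p)$raw_score,
                 oracle_local(strsplit(a, "")[[1]], strsplit(b, "")[[1]], B),
                 info = paste(a, b))
  }
})

test_that("global score is symmetric and local relaxes global", {
  set.seed(7)
  for (k in 1:10) {
    a <- rand_prot(60, rownames(B))
    b <- rand_prot(60, rownames(B))
    expect_equal(global_align(a, b, p)$raw_score,
                 global_align(b, a, p)$raw_score)
    expect_gte(local_align(a, b, p)$raw_score,
               global_align(a, b, p)$raw_score)
  }
})

test_that("aligned rows degap to their inputs and never stack two gaps", {
  set.seed(11)
  for (k in 1:10) {
    a <- rand_prot(sample(5:40, 1), rownames(B))
    b <- rand_prot(sample(5:40, 1), rownames(B))
    aln <- global_align(a, b, p)
    expect_identical(gsub("-", "", aln$aligned_query), a)
    expect_identical(gsub("-", "", aln$aligned_subject), b)
    qa <- strsplit(aln$aligned_query, "")[[1]]
    sa <- strsplit(aln$aligned_subject, "")[[1]]
    expect_false(any(qa == "-" & sa == "-"))
  }
})

test_that("percent identity uses the shorter-sequence denominator", {
  a <- global_align("AAAAAAAAAA", "AAAAAAAAAA", p)
  expect_equal(percent_identity(a, 10, 10), 1.0)
  b <- global_align("AAAA", "AAAT", p)
  expect_equal(percent_identity(b, 4, 4), 0.75)
  d <- global_align("AAAA", "AAAAAAAA", p)
  expect_equal(percent_identity(d, 4, 8), 1.0)   # 4 identities / min(4, 8)
  expect_error(percent_identity(local_align("A", "D", p), 1, 1), "empty")
})

test_that("coverage reports span fractions and errors on zero-length input", {
  a <- global_align("ACDEFG", "ACDEFG", p)
  expect_equal(unname(coverage(a, 6, 6)), c(1, 1))
  l <- local_align("A", "D", p)
  expect_equal(unname(coverage(l, 1, 1)), c(0, 0))
  expect_error(coverage(a, 0, 6), "zero-length")
})

test_that("E-values follow K m n exp(-lambda S) and decrease in the score", {
  expect_equal(evalue(0, 100, 100, p), 0.041 * 1e4)
  expect_equal(evalue(100, 100, 100, p),
               0.041 * 1e4 * exp(-0.267 * 100), tolerance = 1e-12)
  expect_lt(evalue(61, 200, 300, p), evalue(60, 200, 300, p))
})

test_that("substitution matrices round-trip through NCBI text format", {
  path <- withr::local_tempfile(fileext = ".mat")
  lines <- c("# test matrix", paste(" ", paste(rownames(B), collapse = "  ")))
  for (r in rownames(B))
    lines <- c(lines, paste(r, paste(B[r, ], collapse = " ")))
  writeLines(lines, path)
  m <- read_score_matrix(path)
  expect_identical(m, B)
})

test_that("non-amino-acid input is rejected", {
  expect_error(global_align("ABZ1", "AAA", p), "non-amino-acid")
})
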