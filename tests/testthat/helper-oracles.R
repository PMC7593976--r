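# Independent oracles used by the tests. These deliberately avoid the
# package's DP kernels: alignments are scored by exhaustive enumeration of
# all gapped alignments, profile scores by exhaustive enumeration of all
# legal state paths.

# exhaustive enumeration of global affine-gap alignments; gap of length L
# costs open + L*extend
oracle_global <- function(a, b, smat, open = 11, extend = 1) {
  m <- length(a); n <- length(b)
  best <- -Inf
  rec <- function(i, j, last, sc) {
    if (i > m && j > n) {
      if (sc > best) best <<- sc
      return(invisible())
    }
    if (i <= m && j <= n)
      rec(i + 1, j + 1, "M", sc + smat[a[i], b[j]])
    if (i <= m)
      rec(i + 1, j, "X", sc - extend - if (last == "X") 0 else open)
    if (j <= n)
      rec(i, j + 1, "Y", sc - extend - if (last == "Y") 0 else open)
  }
  rec(1, 1, "S", 0)
  best
}

# exhaustive local score: best global score over all substring pairs, floored
# at the empty alignment
oracle_local <- function(a, b, smat, open = 11, extend = 1) {
  m <- length(a); n <- length(b)
  best <- 0
  for (i0 in seq_len(m)) for (j0 in seq_len(n))
    for (i1 in i0:m) for (j1 in j0:n) {
      s <- oracle_global(a[i0:i1], b[j0:j1], smat, open, extend)
      if (s > best) best <- s
    }
  best
}

# exhaustive glocal profile Viterbi: enumerate all state paths through match
# positions 1..L with delete and (internal) insert states, free null-scored
# flanks, and exit transitions from row L
oracle_viterbi <- function(em, tl, x) {
  L <- nrow(em); n <- length(x)
  best <- -Inf
  rec <- function(j, i, prev, sc) {
    if (j == L + 1) {
      ex <- switch(prev, M = tl[L + 1, 1], I = tl[L + 1, 4], D = tl[L + 1, 6])
      if (sc + ex > best) best <<- sc + ex
      return(invisible())
    }
    row <- j
    if (i < n) {
      tm <- switch(prev, M = tl[row, 1], I = tl[row, 4], D = tl[row, 6])
      rec(j + 1, i + 1, "M", sc + tm + em[j, x[i + 1] + 1])
    }
    td <- switch(prev, M = tl[row, 2], I = NA_real_, D = tl[row, 7])
    if (!is.na(td) && is.finite(td)) rec(j + 1, i, "D", sc + td)
    if (i < n && prev %in% c("M", "I")) {
      ti <- if (prev == "M") tl[row, 3] else tl[row, 5]
      if (is.finite(ti)) rec(j, i + 1, "I", sc + ti)
    }
  }
  for (f in 0:n) rec(1, f, "M", 0)
  unname(best)
}

# per-site proportion of differing residues between equal-length sequences
pdist <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  mean(ca != cb)
}

rand_prot <- function(n, alphabet = c("A", "C", "D", "W")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
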