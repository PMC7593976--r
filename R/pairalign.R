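# Pairwise protein alignment: global/local affine-gap DP, identity, coverage
# and an analytic Karlin-Altschul-style E-value. This is the computational
# stand-in for every BLASTP step of the original workflow.

#' Alignment parameters
#'
#' Bundles the substitution matrix, affine gap penalties and the
#' Karlin-Altschul constants used for analytic E-values. The defaults are the
#' gapped-BLOSUM62 BLAST defaults (gap open 11, extend 1, lambda 0.267 nats
#' per raw-score unit, K 0.041). A gap of length L costs
#' \code{gap_open + L * gap_extend}.
#'
#' The E-value constants are a calibration stand-in: no edge-effect or
#' composition correction is applied, so absolute E-values will not match
#' NCBI BLAST. Cutoff-based conclusions should be read with that in mind.
#'
#' @param substitution_matrix 20x20 integer score matrix with amino-acid
#'   dimnames; defaults to BLOSUM62 (from Biostrings).
#' @param gap_open positive gap-opening penalty.
#' @param gap_extend positive gap-extension penalty.
#' @param lambda Karlin-Altschul lambda (nats per raw-score unit).
#' @param K Karlin-Altschul K.
#' @return an object of class \code{align_params}.
#' @export
align_params <- function(substitution_matrix = NULL, gap_open = 11,
                         gap_extend = 1, lambda = 0.267, K = 0.041) {
  if (is.null(substitution_matrix)) substitution_matrix <- blosum62()
  m <- substitution_matrix
  stopifnot(is.matrix(m), nrow(m) == ncol(m),
            !is.null(rownames(m)), identical(rownames(m), colnames(m)))
  if (!(gap_open >= gap_extend && gap_extend >= 1))
    stop("require gap_open >= gap_extend >= 1")
  if (lambda <= 0 || K <= 0) stop("lambda and K must be positive")
  structure(list(matrix = m, alphabet = rownames(m),
                 gap_open = gap_open, gap_extend = gap_extend,
                 lambda = lambda, K = K),
            class = "align_params")
}

# BLOSUM62 restricted to the 20 standard residues, cached per session
.blosum_cache <- new.env(parent = emptyenv())
blosum62 <- function() {
  if (is.null(.blosum_cache$m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .blosum_cache$m <- e$BLOSUM62[AA_ALPHABET, AA_ALPHABET]
  }
  .blosum_cache$m
}

#' Read a substitution matrix in NCBI text format
#'
#' Parses the plain-text matrix format used by NCBI BLAST (comment lines start
#' with \code{#}; first non-comment row is the column alphabet).
#'
#' @param path path to the matrix file.
#' @return an integer score matrix with residue dimnames.
#' @export
read_score_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  cols <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- lapply(lines[-1], function(l) strsplit(trimws(l), "\\s+")[[1]])
  lab <- vapply(rows, `[`, character(1), 1)
  m <- t(vapply(rows, function(r) as.integer(r[-1]), integer(length(cols))))
  dimnames(m) <- list(lab, cols)
  keep <- intersect(AA_ALPHABET, lab)
  m[keep, keep]
}

new_alignment <- function(raw, pat_a, pat_b, a, b, spans, mode) {
  chars_a <- strsplit(a, "")[[1]]
  chars_b <- strsplit(b, "")[[1]]
  fill <- function(pat, chars, offset) {
    p <- strsplit(pat, "")[[1]]
    k <- offset
    vapply(p, function(c) {
      if (c == "-") "-" else { k <<- k + 1L; chars[k] }
    }, character(1), USE.NAMES = FALSE)
  }
  aq <- paste(fill(pat_a, chars_a, spans[1]), collapse = "")
  as_ <- paste(fill(pat_b, chars_b, spans[3]), collapse = "")
  structure(list(raw_score = raw, aligned_query = aq, aligned_subject = as_,
                 query_span = c(spans[1], spans[2]),
                 subject_span = c(spans[3], spans[4]), mode = mode),
            class = "alignment")
}

#' Optimal global (Needleman-Wunsch) alignment with affine gaps
#'
#' Traceback ties are broken by preferring match/mismatch over a gap in the
#' subject over a gap in the query, so alignments are byte-reproducible.
#' Aligning against an empty sequence yields the forced all-gap alignment.
#'
#' @param a,b protein sequences (single strings).
#' @param params an \code{\link{align_params}} object.
#' @return an object of class \code{alignment} with fields \code{raw_score},
#'   \code{aligned_query}, \code{aligned_subject}, half-open 0-based
#'   \code{query_span}/\code{subject_span} and \code{mode}.
#' @export
global_align <- function(a, b, params = align_params()) {
  ia <- encode_seq(a, params$alphabet)
  ib <- encode_seq(b, params$alphabet)
  if (length(ia) == 0L && length(ib) == 0L)
    return(structure(list(raw_score = 0, aligned_query = "",
                          aligned_subject = "", query_span = c(0L, 0L),
                          subject_span = c(0L, 0L), mode = "global"),
                     class = "alignment"))
  if (length(ia) == 0L || length(ib) == 0L) {
    L <- max(length(ia), length(ib))
    score <- -(params$gap_open + L * params$gap_extend)
    pat_a <- if (length(ia) == 0L) strrep("-", L) else a
    pat_b <- if (length(ib) == 0L) strrep("-", L) else b
    return(structure(list(raw_score = score, aligned_query = pat_a,
                          aligned_subject = pat_b,
                          query_span = c(0L, length(ia)),
                          subject_span = c(0L, length(ib)), mode = "global"),
                     class = "alignment"))
  }
  r <- .cpp_global_align(ia, ib, params$matrix, params$gap_open,
                         params$gap_extend)
  new_alignment(r$score, r$pat_a, r$pat_b, a, b,
                c(r$a_start, r$a_end, r$b_start, r$b_end), "global")
}

#' Optimal local (Smith-Waterman) alignment with affine gaps
#'
#' Scores are floored at zero; when no residue pair scores positively the
#' result is the empty alignment with score 0.
#'
#' @inheritParams global_align
#' @return an \code{alignment} object (see \code{\link{global_align}}).
#' @export
local_align <- function(a, b, params = align_params()) {
  ia <- encode_seq(a, params$alphabet)
  ib <- encode_seq(b, params$alphabet)
  if (length(ia) == 0L || length(ib) == 0L)
    return(structure(list(raw_score = 0, aligned_query = "",
                          aligned_subject = "", query_span = c(0L, 0L),
                          subject_span = c(0L, 0L), mode = "local"),
                     class = "alignment"))
  r <- .cpp_local_align(ia, ib, params$matrix, params$gap_open,
                        params$gap_extend)
  new_alignment(r$score, r$pat_a, r$pat_b, a, b,
                c(r$a_start, r$a_end, r$b_start, r$b_end), "local")
}

# batch of raw local scores between two sets of sequences (C++ kernel)
local_score_matrix <- function(seqs_a, seqs_b, params = align_params()) {
  ea <- lapply(seqs_a, encode_seq, alphabet = params$alphabet)
  eb <- lapply(seqs_b, encode_seq, alphabet = params$alphabet)
  m <- .cpp_sw_score_matrix(ea, eb, params$matrix, params$gap_open,
                            params$gap_extend)
  dimnames(m) <- list(names(seqs_a), names(seqs_b))
  m
}

#' Percent identity of an alignment (CD-HIT convention)
#'
#' Identical aligned residue pairs divided by the length of the shorter
#' sequence — the convention of CD-HIT, whose identity levels (95%, 80%) the
#' redundancy-reduction steps reproduce.
#'
#' @param aln an \code{alignment}.
#' @param a_len,b_len ungapped lengths of the two input sequences.
#' @return a fraction in [0, 1].
#' @export
percent_identity <- function(aln, a_len, b_len) {
  if (nchar(aln$aligned_query) == 0L) stop("empty alignment has no identity")
  qa <- strsplit(aln$aligned_query, "")[[1]]
  sa <- strsplit(aln$aligned_subject, "")[[1]]
  ident <- sum(qa == sa & qa != "-")
  ident / min(a_len, b_len)
}

#' Alignment coverage of query and subject
#'
#' @inheritParams percent_identity
#' @return numeric length-2 vector: span length over sequence length for the
#'   query and the subject.
#' @export
coverage <- function(aln, a_len, b_len) {
  if (a_len == 0L || b_len == 0L) stop("zero-length input sequence")
  c(query = unname((aln$query_span[2] - aln$query_span[1]) / a_len),
    subject = unname((aln$subject_span[2] - aln$subject_span[1]) / b_len))
}

#' Analytic E-value for a raw alignment score
#'
#' \eqn{E = K m n exp(-lambda S)} with the constants carried by
#' \code{params}; strictly decreasing in the score. No edge-effect
#' correction is applied.
#'
#' @param raw_score raw alignment score.
#' @param m,n lengths (residues) of the two sequences or search spaces.
#' @inheritParams global_align
#' @return the expected number of chance alignments with score >= raw_score.
#' @export
evalue <- function(raw_score, m, n, params = align_params()) {
  stopifnot(m >= 1, n >= 1)
  params$K * m * n * exp(-params$lambda * raw_score)
}
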