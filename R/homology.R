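# Best-hit search, reciprocal-best-hit orthology, mutual-connection counting
# and fixed-threshold sequence search (the UpxY-style query).

genome_seqs <- function(genome) {
  setNames(genome$genes$protein_sequence, genome$genes$gene_id)
}

#' Best-scoring hit of a query gene in a target genome
#'
#' The hit with maximal local raw score (ties broken by lexicographic gene
#' id); \code{NULL} when the best hit's analytic E-value exceeds
#' \code{evalue_max}.
#'
#' @param query_seq query protein sequence (single string).
#' @param target a \code{genome}.
#' @param params an \code{\link{align_params}}.
#' @param evalue_max maximum E-value for a reportable hit.
#' @return list(gene_id, raw_score, evalue) or NULL.
#' @export
best_hit <- function(query_seq, target, params = align_params(),
                     evalue_max = 1e-5) {
  seqs <- genome_seqs(target)
  if (length(seqs) == 0) return(NULL)
  sc <- local_score_matrix(setNames(list(query_seq), "q"), seqs, params)[1, ]
  ord <- order(-sc, names(sc))
  top <- ord[1]
  ev <- evalue(sc[top], nchar(query_seq), nchar(seqs[top]), params)
  if (ev > evalue_max) return(NULL)
  list(gene_id = names(seqs)[top], raw_score = unname(sc[top]),
       evalue = unname(ev))
}

#' Reciprocal best hits between two genomes
#'
#' Pairs of genes that are each other's best-scoring match in the other
#' genome (both directions passing the E-value cutoff). Symmetric in
#' argument order.
#'
#' @param ga,gb \code{genome} objects.
#' @inheritParams best_hit
#' @return data frame gene_a, gene_b, score_ab, score_ba (gene_a from
#'   \code{ga}).
#' @export
reciprocal_best_hits <- function(ga, gb, params = align_params(),
                                 evalue_max = 1e-5) {
  sa <- genome_seqs(ga); sb <- genome_seqs(gb)
  empty <- data.frame(gene_a = character(0), gene_b = character(0),
                      score_ab = numeric(0), score_ba = numeric(0))
  if (length(sa) == 0 || length(sb) == 0) return(empty)
  sc <- local_score_matrix(sa, sb, params)
  best_of <- function(scores, ids) {
    ord <- order(-scores, ids)
    ord[1]
  }
  ids_a <- names(sa); ids_b <- names(sb)
  best_ab <- apply(sc, 1, function(r) best_of(r, ids_b))
  best_ba <- apply(sc, 2, function(c) best_of(c, ids_a))
  rows <- list()
  for (i in seq_along(ids_a)) {
    j <- best_ab[i]
    if (best_ba[j] != i) next
    s <- sc[i, j]
    ev_ab <- evalue(s, nchar(sa[i]), nchar(sb[j]), params)
    if (ev_ab > evalue_max) next
    rows[[length(rows) + 1L]] <-
      data.frame(gene_a = ids_a[i], gene_b = ids_b[j],
                 score_ab = s, score_ba = s, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mutual RBH connections among representatives
#'
#' For each representative (a gene in its genome), the number of other
#' representatives with which it forms a reciprocal best hit.
#'
#' @param reps list of list(gene_id, genome): the representatives.
#' @inheritParams best_hit
#' @return named integer vector of counts.
#' @export
mutual_connections <- function(reps, params = align_params(),
                               evalue_max = 1e-5) {
  if (length(reps) < 2) stop("need at least 2 representatives")
  ids <- vapply(reps, `[[`, character(1), "gene_id")
  n <- length(reps)
  counts <- setNames(integer(n), ids)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    rbh <- reciprocal_best_hits(reps[[i]]$genome, reps[[j]]$genome,
                                params, evalue_max)
    hit <- any(rbh$gene_a == ids[i] & rbh$gene_b == ids[j])
    if (hit) {
      counts[i] <- counts[i] + 1L
      counts[j] <- counts[j] + 1L
    }
  }
  counts
}

#' Fixed-threshold sequence search
#'
#' All (query, gene) local alignments with E-value strictly below
#' \code{evalue_max}, with score, identity and coverage columns.
#'
#' @param queries named character vector of query sequences.
#' @param db list of \code{genome} objects (or a \code{genome_world}).
#' @param evalue_max strict E-value threshold (default 1e-10).
#' @param params an \code{\link{align_params}}.
#' @return data frame query_id, gene_id, genome_id, raw_score, evalue,
#'   identity, query_coverage, subject_coverage.
#' @export
sequence_search <- function(queries, db, evalue_max = 1e-10,
                            params = align_params()) {
  stopifnot(evalue_max > 0)
  if (inherits(db, "genome_world")) db <- db$genomes
  empty <- data.frame(query_id = character(0), gene_id = character(0),
                      genome_id = character(0), raw_score = numeric(0),
                      evalue = numeric(0), identity = numeric(0),
                      query_coverage = numeric(0),
                      subject_coverage = numeric(0))
  if (length(db) == 0 || length(queries) == 0) return(empty)
  rows <- list()
  for (gn in db) {
    seqs <- genome_seqs(gn)
    sc <- local_score_matrix(queries, seqs, params)
    for (qi in seq_along(queries)) for (si in seq_along(seqs)) {
      ev <- evalue(sc[qi, si], nchar(queries[qi]), nchar(seqs[si]), params)
      if (ev >= evalue_max) next
      aln <- local_align(queries[[qi]], seqs[[si]], params)
      cov <- coverage(aln, nchar(queries[qi]), nchar(seqs[si]))
      rows[[length(rows) + 1L]] <- data.frame(
        query_id = names(queries)[qi], gene_id = names(seqs)[si],
        genome_id = gn$genome_id, raw_score = aln$raw_score, evalue = ev,
        identity = percent_identity(aln, nchar(queries[qi]), nchar(seqs[si])),
        query_coverage = unname(cov["query"]),
        subject_coverage = unname(cov["subject"]), stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
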