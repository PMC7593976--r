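# Phyletic profiling: presence/absence matrices from profile scans,
# per-taxon hit percentages, the multi-marker genome-completeness screen and
# the conserved-operon context check.

#' Presence matrix from per-model hit tables
#'
#' Counts member-zone hits per genome and model; candidate-zone hits do not
#' count as presence.
#'
#' @param hit_tables named list model name -> \code{\link{scan_proteomes}}
#'   data frame.
#' @param genomes list of \code{genome} objects (or a \code{genome_world}).
#' @return integer matrix genomes x models.
#' @export
presence_matrix <- function(hit_tables, genomes) {
  if (inherits(genomes, "genome_world")) genomes <- genomes$genomes
  ids <- vapply(genomes, `[[`, character(1), "genome_id")
  M <- matrix(0L, length(ids), length(hit_tables),
              dimnames = list(ids, names(hit_tables)))
  for (m in names(hit_tables)) {
    ht <- hit_tables[[m]]
    ht <- ht[ht$zone == "member", , drop = FALSE]
    if (nrow(ht) == 0) next
    unknown <- setdiff(unique(ht$genome_id), ids)
    if (length(unknown) > 0)
      stop("hit table references unknown genome(s): ",
           paste(unknown, collapse = ", "))
    tab <- table(ht$genome_id)
    M[names(tab), m] <- as.integer(tab)
  }
  M
}

#' Per-taxon percentage of genomes with a hit
#'
#' For every taxon with at least \code{min_genomes} genomes: the fraction of
#' its genomes with at least one member-zone hit; smaller taxa are omitted.
#'
#' @param matrix a \code{\link{presence_matrix}}.
#' @param taxonomy named character vector genome id -> taxon.
#' @param model column of the matrix to evaluate.
#' @param min_genomes minimum taxon size (default 10).
#' @return named numeric vector taxon -> fraction.
#' @export
percent_hits <- function(matrix, taxonomy, model, min_genomes = 10) {
  stopifnot(min_genomes >= 1, model %in% colnames(matrix))
  taxa <- split(names(taxonomy), taxonomy)
  out <- numeric(0)
  for (tx in names(taxa)) {
    g <- intersect(taxa[[tx]], rownames(matrix))
    if (length(g) < min_genomes) next
    out[tx] <- mean(matrix[g, model] >= 1)
  }
  out
}

#' Multi-marker genome completeness screen
#'
#' Genomes with zero hits for the focal model but at least one hit for every
#' control model: likely true absences rather than incomplete assemblies.
#'
#' @param matrix a \code{\link{presence_matrix}}.
#' @param focal focal model name.
#' @param controls control model names.
#' @return character vector of genome ids.
#' @export
completeness_screen <- function(matrix, focal, controls) {
  if (!(focal %in% colnames(matrix))) stop("focal model not in matrix")
  if (!all(controls %in% colnames(matrix)))
    stop("control model(s) missing from matrix")
  ok <- matrix[, focal] == 0 &
    rowSums(matrix[, controls, drop = FALSE] >= 1) == length(controls)
  rownames(matrix)[ok]
}

#' Conserved-operon context check
#'
#' Finds consecutive same-contig, same-strand gene runs matching an ordered
#' family pattern with one optional slot, and reports each locus as intact
#' (optional slot filled) or gapped (slot absent) — the protein-level
#' analogue of inspecting secE-nusG?-rplK-rplA loci.
#'
#' @param genome a \code{genome} with truth family labels, or a gene data
#'   frame with columns contig_id, index, strand and a family column.
#' @param pattern character vector of family labels in order.
#' @param optional_slot index into \code{pattern} of the optional element.
#' @param family_of optional named vector gene_id -> family label used
#'   instead of the genome's truth labels (e.g., from profile scans).
#' @return data frame contig_id, start_index, status (intact/gapped).
#' @export
operon_context <- function(genome, pattern, optional_slot = 2,
                           family_of = NULL) {
  stopifnot(length(pattern) >= 2, optional_slot >= 1,
            optional_slot <= length(pattern))
  genes <- if (inherits(genome, "genome")) genome$genes else genome
  fam <- if (!is.null(family_of)) unname(family_of[genes$gene_id])
         else genes$truth_family
  fam[is.na(fam)] <- ""
  out <- list()
  for (ct in unique(genes$contig_id)) {
    sel <- genes$contig_id == ct
    ord <- order(genes$index[sel])
    f <- fam[sel][ord]
    s <- genes$strand[sel][ord]
    idx <- genes$index[sel][ord]
    n <- length(f)
    full <- pattern
    gapped <- pattern[-optional_slot]
    match_run <- function(target, start) {
      k <- length(target)
      if (start + k - 1 > n) return(FALSE)
      win <- start:(start + k - 1)
      all(f[win] == target) && length(unique(s[win])) == 1
    }
    for (st in seq_len(n)) {
      if (match_run(full, st)) {
        out[[length(out) + 1L]] <- data.frame(
          contig_id = ct, start_index = idx[st], status = "intact",
          stringsAsFactors = FALSE)
      } else if (match_run(gapped, st)) {
        out[[length(out) + 1L]] <- data.frame(
          contig_id = ct, start_index = idx[st], status = "gapped",
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(contig_id = character(0), start_index = integer(0),
                      status = character(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
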