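# Gene-neighborhood extraction around focal genes and COG-category
# enrichment per cluster.

#' Neighbors of a gene
#'
#' Up to \code{flank} genes on each side of the focal gene on its contig
#' (strand-agnostic), excluding the focal gene, truncated at contig ends.
#'
#' @param genome a \code{genome}.
#' @param gene_id focal gene id.
#' @param flank genes per side (default 5).
#' @return data frame of neighbor gene rows, ordered by index.
#' @export
gene_neighbors <- function(genome, gene_id, flank = 5) {
  stopifnot(flank >= 1)
  genes <- genome$genes
  i <- which(genes$gene_id == gene_id)
  if (length(i) != 1) stop("gene not found in genome: ", gene_id)
  ct <- genes$contig_id[i]
  on_ct <- which(genes$contig_id == ct)
  on_ct <- on_ct[order(genes$index[on_ct])]
  pos <- which(on_ct == i)
  lo <- max(1, pos - flank); hi <- min(length(on_ct), pos + flank)
  sel <- on_ct[setdiff(lo:hi, pos)]
  genes[sel, , drop = FALSE]
}

#' Neighborhood COG matrix per cluster
#'
#' Pools the COG categories of the neighbors of every clustered focal gene
#' and reports raw counts plus counts normalized by the number of focal
#' genes per cluster. Genes with category "-" are counted in an
#' \code{unassigned} column. Focal genes never count in their own windows.
#'
#' @param clusters named vector gene id -> cluster label.
#' @param genomes list of \code{genome}s (or a \code{genome_world}).
#' @param flank genes per side (default 5).
#' @return object of class \code{cog_matrix}: list(raw, normalized,
#'   refs_per_cluster); matrices are clusters x categories.
#' @export
cog_matrix <- function(clusters, genomes, flank = 5) {
  if (inherits(genomes, "genome_world")) genomes <- genomes$genomes
  if (length(clusters) == 0) stop("no clustered genes")
  gene_home <- unlist(lapply(unname(genomes), function(gn)
    setNames(rep(gn$genome_id, nrow(gn$genes)), gn$genes$gene_id)))
  missing <- setdiff(names(clusters), names(gene_home))
  if (length(missing) > 0)
    stop("clustered gene(s) not locatable: ", paste(missing, collapse = ", "))
  genomes_by_id <- setNames(genomes,
                            vapply(genomes, `[[`, character(1), "genome_id"))
  labs <- sort(unique(clusters))
  cats <- c(sort(unique(c(COG_LETTERS,
                          unlist(lapply(genomes, function(gn)
                            setdiff(gn$genes$cog_category, "-")))))),
            "unassigned")
  raw <- matrix(0, length(labs), length(cats),
                dimnames = list(labs, cats))
  refs <- setNames(integer(length(labs)), labs)
  foci <- vapply(split(names(clusters), clusters), length, integer(1))
  if (any(foci == 0)) stop("empty cluster")
  for (gid in names(clusters)) {
    cl <- clusters[[gid]]
    refs[cl] <- refs[cl] + 1L
    nb <- gene_neighbors(genomes_by_id[[gene_home[[gid]]]], gid, flank)
    # other focal genes inside the window still count as neighbors; only the
    # focal gene itself is excluded
    cogs <- ifelse(nb$cog_category == "-", "unassigned", nb$cog_category)
    tab <- table(cogs)
    raw[cl, names(tab)] <- raw[cl, names(tab)] + as.integer(tab)
  }
  normalized <- sweep(raw, 1, refs, "/")
  structure(list(raw = raw, normalized = normalized,
                 refs_per_cluster = refs),
            class = "cog_matrix")
}

#' Per-cluster COG percentages
#'
#' Row-normalized raw neighbor counts: (raw count of a category) / (total
#' neighbor genes of the cluster); each row sums to one.
#'
#' @param matrix a \code{\link{cog_matrix}}.
#' @return matrix of fractions, clusters x categories.
#' @export
cog_percentages <- function(matrix) {
  tot <- rowSums(matrix$raw)
  if (any(tot == 0)) stop("cluster with zero neighbor genes")
  sweep(matrix$raw, 1, tot, "/")
}

#' Export a COG matrix as TSV
#' @param matrix a \code{cog_matrix}.
#' @param path file path.
#' @param what \code{"normalized"} or \code{"raw"}.
#' @export
write_cog_matrix <- function(matrix, path, what = c("normalized", "raw")) {
  what <- match.arg(what)
  m <- matrix[[what]]
  df <- data.frame(cluster = rownames(m), as.data.frame(m),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}
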