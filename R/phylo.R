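# Distance-based tree inference and tree-level statistics: topology
# congruence (the HGT signal) and the longest-path branch-length-sum rate
# comparison. Trees are ape "phylo" objects throughout; neighbor joining
# replaces the original workflow's maximum-likelihood inference, so only
# topology-level conclusions are drawn from these trees.

#' Pairwise distance matrix from an MSA
#'
#' p-distance with pairwise deletion of gap columns; optional Poisson
#' correction \eqn{d = -ln(1 - min(p, p_max))}.
#'
#' @param msa an \code{msa} (>= 3 rows).
#' @param correction \code{"none"} or \code{"poisson"}.
#' @param p_max cap applied to p before the Poisson transform.
#' @return symmetric numeric matrix with sequence ids as dimnames.
#' @export
distance_matrix <- function(msa, correction = c("poisson", "none"),
                            p_max = 0.95) {
  correction <- match.arg(correction)
  if (length(msa$rows) < 3) stop("need at least 3 sequences")
  mat <- do.call(rbind, lapply(msa$rows, function(r) strsplit(r, "")[[1]]))
  n <- nrow(mat)
  D <- matrix(0, n, n, dimnames = list(msa$ids, msa$ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- mat[i, ] != "-" & mat[j, ] != "-"
    if (!any(ok))
      stop(sprintf("no comparable columns between %s and %s",
                   msa$ids[i], msa$ids[j]))
    p <- mean(mat[i, ok] != mat[j, ok])
    d <- if (correction == "poisson") -log(1 - min(p, p_max)) else p
    D[i, j] <- d; D[j, i] <- d
  }
  D
}

#' Neighbor-joining tree
#'
#' Standard NJ on a symmetric distance matrix (via ape), with negative
#' branch lengths clamped to zero. The result is unrooted.
#'
#' @param D symmetric distance matrix with zero diagonal (>= 3 taxa).
#' @return an \code{ape::phylo} tree.
#' @export
neighbor_joining <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D) || !isTRUE(all.equal(D, t(D))))
    stop("distance matrix must be symmetric")
  if (nrow(D) < 3) stop("need at least 3 taxa")
  tr <- ape::nj(D)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Robinson-Foulds distance between two trees
#'
#' Size of the symmetric difference of the non-trivial splits, plus a
#' normalized value: raw divided by the total number of internal splits in
#' both trees (2(n-3) for two binary unrooted trees).
#'
#' @param t1,t2 \code{phylo} trees over the same leaf set.
#' @return c(raw, normalized).
#' @export
robinson_foulds <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have different leaf sets")
  t1 <- ape::unroot(t1); t2 <- ape::unroot(t2)
  raw <- phangorn::RF.dist(t1, t2, check.labels = TRUE)
  n_splits <- function(t) {
    # internal edges of the unrooted tree = non-trivial splits
    sum(t$edge[, 2] > length(t$tip.label))
  }
  tot <- n_splits(t1) + n_splits(t2)
  norm <- if (tot == 0) 0 else raw / tot
  c(raw = raw, normalized = norm)
}

#' Branch-length sum of the longest leaf-to-leaf path (tree diameter)
#'
#' @param t a \code{phylo} tree with >= 2 leaves.
#' @param from_root if TRUE, return the maximum root-to-leaf depth instead
#'   of the leaf-to-leaf diameter.
#' @return path length.
#' @export
longest_path_sum <- function(t, from_root = FALSE) {
  n <- length(t$tip.label)
  if (n < 2) stop("tree has fewer than 2 leaves")
  if (from_root) return(max(ape::node.depth.edgelength(t)[seq_len(n)]))
  dm <- ape::dist.nodes(t)[seq_len(n), seq_len(n)]
  max(dm)
}

#' Midpoint rooting
#'
#' Roots the tree at the midpoint of its diameter path.
#'
#' @param t a \code{phylo} tree with >= 2 leaves.
#' @return a rooted \code{phylo} tree.
#' @export
midpoint_root <- function(t) {
  if (length(t$tip.label) < 2) stop("tree has fewer than 2 leaves")
  if (longest_path_sum(t) == 0) {
    warning("zero-diameter tree; rooting at an arbitrary node")
    return(t)
  }
  phangorn::midpoint(t)
}

#' Neighbor-joining tree from a family of sequences
#'
#' Convenience wrapper: stack (indel-free) or center-star align, compute
#' Poisson-corrected distances, run NJ.
#'
#' @param seqs named character vector (>= 3).
#' @param params an \code{\link{align_params}} (used only if lengths differ).
#' @return an \code{ape::phylo} tree.
#' @export
family_tree <- function(seqs, params = align_params()) {
  msa <- if (length(unique(nchar(seqs))) == 1) msa_from_stack(seqs)
         else center_star_msa(seqs, params)
  neighbor_joining(distance_matrix(msa, "poisson"))
}

#' Concatenated single-copy marker tree
#'
#' Column-wise concatenation of per-family alignments (each genome must have
#' exactly one member of each marker family), Poisson distances, NJ — the
#' stand-in for a many-marker genome tree.
#'
#' @param genomes list of \code{genome} objects (or a \code{genome_world}).
#' @param marker_families list of named character vectors: per family,
#'   sequences named by genome id.
#' @param correction distance correction, as in
#'   \code{\link{distance_matrix}}.
#' @return an \code{ape::phylo} tree with genome ids as leaves.
#' @export
concat_marker_tree <- function(genomes, marker_families,
                               correction = "poisson") {
  if (inherits(genomes, "genome_world")) genomes <- genomes$genomes
  ids <- vapply(genomes, `[[`, character(1), "genome_id")
  for (k in seq_along(marker_families)) {
    fam <- marker_families[[k]]
    cnt <- table(factor(names(fam), levels = ids))
    if (any(cnt != 1)) {
      bad <- names(cnt)[cnt != 1][1]
      stop(sprintf("genome %s has %d members of marker family %d (need 1)",
                   bad, cnt[bad], k))
    }
  }
  concat <- vapply(ids, function(g)
    paste(vapply(marker_families, function(fam) fam[[g]], character(1)),
          collapse = ""), character(1))
  msa <- msa_from_stack(concat)
  neighbor_joining(distance_matrix(msa, correction))
}
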