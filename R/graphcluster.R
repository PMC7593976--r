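# Stepwise clustering of paralog sequences: greedy redundancy reduction,
# reciprocal all-vs-all similarity-graph construction, and Markov clustering
# (MCL) implemented from scratch on a dense column-stochastic matrix.

#' Clustering configuration
#'
#' Defaults follow the reference workflow: redundancy reduction at 95%
#' identity, graph edges admitted at E <= 5e-30 with >= 80% coverage in both
#' directions and on both sequences, and MCL with inflation 5.
#'
#' @param redundancy_identity identity level for redundancy reduction.
#' @param evalue_max maximum E-value for a graph edge.
#' @param coverage_min minimum alignment coverage for a graph edge.
#' @param inflation MCL inflation (entrywise power).
#' @param expansion MCL expansion (matrix power).
#' @param prune_threshold entries below this are zeroed each iteration.
#' @param convergence_tol stop when the largest entry change falls below.
#' @param max_iterations iteration cap (returns with a warning flag beyond).
#' @param evalue_floor floor applied before the log-transform of E-values.
#' @return an object of class \code{cluster_config}.
#' @export
cluster_config <- function(redundancy_identity = 0.95, evalue_max = 5e-30,
                           coverage_min = 0.80, inflation = 5, expansion = 2,
                           prune_threshold = 1e-6, convergence_tol = 1e-8,
                           max_iterations = 200, evalue_floor = 1e-180) {
  stopifnot(redundancy_identity > 0, redundancy_identity <= 1,
            inflation > 1, expansion >= 2)
  structure(list(redundancy_identity = redundancy_identity,
                 evalue_max = evalue_max, coverage_min = coverage_min,
                 inflation = inflation, expansion = expansion,
                 prune_threshold = prune_threshold,
                 convergence_tol = convergence_tol,
                 max_iterations = max_iterations,
                 evalue_floor = evalue_floor),
            class = "cluster_config")
}

#' Greedy incremental redundancy reduction (CD-HIT style)
#'
#' Sequences are processed sorted by length descending (ties by id
#' ascending); each joins the first existing representative with global-
#' alignment percent identity (shorter-length denominator) at or above the
#' threshold, otherwise it founds a new representative.
#'
#' @param seqs named character vector.
#' @param identity_threshold identity level in (0, 1].
#' @param params an \code{\link{align_params}}.
#' @return list(representatives, membership): representative ids and a named
#'   map sequence id -> representative id.
#' @export
reduce_redundancy <- function(seqs, identity_threshold = 0.95,
                              params = align_params()) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1)
  if (length(seqs) == 0)
    return(list(representatives = character(0),
                membership = setNames(character(0), character(0))))
  ids <- names(seqs)
  ord <- order(-nchar(seqs), ids)
  reps <- character(0)
  membership <- setNames(character(length(seqs)), ids)
  for (i in ord) {
    placed <- FALSE
    for (r in reps) {
      aln <- global_align(seqs[[r]], seqs[[i]], params)
      pid <- percent_identity(aln, nchar(seqs[[r]]), nchar(seqs[[i]]))
      if (pid >= identity_threshold) {
        membership[ids[i]] <- r
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, ids[i])
      membership[ids[i]] <- ids[i]
    }
  }
  list(representatives = reps, membership = membership)
}

#' Build a reciprocal similarity graph
#'
#' All-vs-all local alignment; the edge (a, b) exists iff the E-values in
#' both directions are at most \code{evalue_max} and coverage is at least
#' \code{coverage_min} on both sequences. The edge weight is
#' \eqn{-log10(mean(E_ab, E_ba))} with the mean floored at
#' \code{evalue_floor} (the graph stores averaged reciprocal E-values; MCL
#' needs larger-is-more-similar, hence the log transform).
#'
#' @param seqs named character vector (>= 2).
#' @param config a \code{\link{cluster_config}}.
#' @param params an \code{\link{align_params}}.
#' @return object of class \code{similarity_graph}: list(nodes, edges) where
#'   edges has node_a, node_b, evalue_ab, evalue_ba, weight.
#' @export
build_similarity_graph <- function(seqs, config = cluster_config(),
                                   params = align_params()) {
  if (length(seqs) < 2) stop("need at least 2 sequences")
  ids <- names(seqs)
  n <- length(seqs)
  sc <- local_score_matrix(seqs, seqs, params)
  lens <- nchar(seqs)
  rows <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    # raw local score is symmetric; the two "directions" differ by the
    # (query, subject) length product entering the E-value — identical for a
    # pair — so reciprocal E-values coincide under the analytic formula.
    # Coverage is direction-specific and needs the explicit alignment.
    s <- sc[i, j]
    ev <- evalue(s, lens[i], lens[j], params)
    if (ev > config$evalue_max) next
    aln <- local_align(seqs[[i]], seqs[[j]], params)
    cov <- coverage(aln, lens[i], lens[j])
    if (cov["query"] < config$coverage_min ||
        cov["subject"] < config$coverage_min) next
    evm <- max(ev, config$evalue_floor)
    rows[[length(rows) + 1L]] <- data.frame(
      node_a = ids[i], node_b = ids[j], evalue_ab = ev, evalue_ba = ev,
      weight = -log10(evm), stringsAsFactors = FALSE)
  }
  edges <- if (length(rows) == 0)
    data.frame(node_a = character(0), node_b = character(0),
               evalue_ab = numeric(0), evalue_ba = numeric(0),
               weight = numeric(0))
  else do.call(rbind, rows)
  rownames(edges) <- NULL
  structure(list(nodes = ids, edges = edges), class = "similarity_graph")
}

#' Markov clustering (MCL)
#'
#' From-scratch MCL on the similarity graph: self-loops are added (weight =
#' the node's maximum incident edge weight, 1 for isolated nodes), the
#' adjacency matrix is column-normalized, and expansion (matrix power) and
#' inflation (entrywise power + renormalization) alternate, with pruning of
#' small entries, until the largest entry change falls below the tolerance.
#' Clusters are the connected components of the attractor structure; nodes
#' attracted to several clusters go to the one with the larger attractor
#' mass (ties to the smaller cluster label). Labels are ordered by
#' descending cluster size, then by lexicographically smallest member.
#'
#' @param graph a \code{similarity_graph}.
#' @param config a \code{\link{cluster_config}}.
#' @return list(clusters: named map node -> cluster label, converged: flag,
#'   iterations).
#' @export
mcl <- function(graph, config = cluster_config()) {
  nodes <- graph$nodes
  n <- length(nodes)
  if (n == 0) stop("empty graph")
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  e <- graph$edges
  if (nrow(e) > 0) {
    for (k in seq_len(nrow(e))) {
      A[e$node_a[k], e$node_b[k]] <- e$weight[k]
      A[e$node_b[k], e$node_a[k]] <- e$weight[k]
    }
  }
  selfw <- apply(A, 1, max)
  selfw[selfw == 0] <- 1
  diag(A) <- selfw
  normalize <- function(M) sweep(M, 2, colSums(M), "/")
  M <- normalize(A)
  converged <- FALSE
  it <- 0L
  while (it < config$max_iterations) {
    it <- it + 1L
    M_old <- M
    P <- M
    for (k in seq_len(config$expansion - 1L)) P <- P %*% M
    P <- P^config$inflation
    M <- normalize(P)
    # prune after normalizing: a normalized column's maximum is at least 1/n,
    # so pruning can never empty a column
    M[M < config$prune_threshold] <- 0
    M <- normalize(M)
    if (max(abs(M - M_old)) < config$convergence_tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("MCL did not converge within max_iterations; returning current state")

  # attractors: nodes with positive return probability
  attract <- which(diag(M) > config$prune_threshold)
  # components of the attractor structure: attractors linked if either flows
  # to the other
  B <- (M[attract, attract, drop = FALSE] > 0) |
    t(M[attract, attract, drop = FALSE] > 0)
  comp <- rep(NA_integer_, length(attract))
  cid <- 0L
  for (s in seq_along(attract)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(B[v, ] & is.na(comp)))
    }
  }
  # assign every node to the attractor cluster with greatest mass in its
  # column (ties -> smaller cluster id)
  assign_cluster <- integer(n)
  for (v in seq_len(n)) {
    mass <- tapply(M[attract, v], comp, sum)
    mass <- mass[order(-mass, as.integer(names(mass)))]
    assign_cluster[v] <- as.integer(names(mass)[1])
  }
  # relabel by descending size then smallest member id
  sizes <- table(assign_cluster)
  firsts <- tapply(nodes, assign_cluster, min)
  ord <- order(-as.integer(sizes[as.character(names(firsts))]),
               firsts)
  relabel <- setNames(seq_along(ord), names(firsts)[ord])
  labels <- paste0("CL", relabel[as.character(assign_cluster)])
  list(clusters = setNames(labels, nodes), converged = converged,
       iterations = it)
}

#' Stepwise clustering
#'
#' Redundancy reduction, similarity-graph construction on the
#' representatives, MCL; members inherit their representative's cluster.
#'
#' @param seqs named character vector (>= 2).
#' @param config a \code{\link{cluster_config}}.
#' @param params an \code{\link{align_params}}.
#' @return list(clusters: named map over all input ids, representatives,
#'   membership, graph, mcl).
#' @export
stepwise_cluster <- function(seqs, config = cluster_config(),
                             params = align_params()) {
  if (length(seqs) < 2) stop("need at least 2 sequences")
  red <- reduce_redundancy(seqs, config$redundancy_identity, params)
  if (length(red$representatives) == 1) {
    # redundancy reduction collapsed everything: trivially one cluster
    graph <- structure(list(nodes = red$representatives,
                            edges = data.frame(node_a = character(0),
                                               node_b = character(0),
                                               evalue_ab = numeric(0),
                                               evalue_ba = numeric(0),
                                               weight = numeric(0))),
                       class = "similarity_graph")
  } else {
    graph <- build_similarity_graph(seqs[red$representatives], config, params)
  }
  m <- mcl(graph, config)
  clusters <- setNames(m$clusters[red$membership[names(seqs)]], names(seqs))
  list(clusters = clusters, representatives = red$representatives,
       membership = red$membership, graph = graph, mcl = m)
}

#' Write a similarity graph in ABC edge-list format
#' @param graph a \code{similarity_graph}.
#' @param path file path.
#' @return the path (write) or a \code{similarity_graph} (read).
#' @export
write_graph_abc <- function(graph, path) {
  lines <- sprintf("%s %s %.6g", graph$edges$node_a, graph$edges$node_b,
                   graph$edges$weight)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_graph_abc
#' @param nodes optional full node set (isolated nodes are absent from ABC
#'   files).
#' @export
read_graph_abc <- function(path, nodes = NULL) {
  lines <- readLines(path)
  parts <- strsplit(lines[nzchar(lines)], "\\s+")
  edges <- data.frame(node_a = vapply(parts, `[`, character(1), 1),
                      node_b = vapply(parts, `[`, character(1), 2),
                      evalue_ab = NA_real_, evalue_ba = NA_real_,
                      weight = as.numeric(vapply(parts, `[`, character(1), 3)),
                      stringsAsFactors = FALSE)
  if (is.null(nodes)) nodes <- sort(unique(c(edges$node_a, edges$node_b)))
  structure(list(nodes = nodes, edges = edges), class = "similarity_graph")
}

#' Write cluster assignments as TSV
#' @param result a \code{\link{stepwise_cluster}} result.
#' @param path file path.
#' @export
write_clusters <- function(result, path) {
  df <- data.frame(sequence_id = names(result$clusters),
                   representative_id = unname(result$membership[names(result$clusters)]),
                   cluster_label = unname(result$clusters),
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}
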