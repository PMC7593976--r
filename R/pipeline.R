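# End-to-end orchestration: world generation, model building, scanning,
# orthology, clustering, trees, functional sites, phyletic profiling and
# neighborhoods, with all artifacts written to an output directory and a
# machine-readable summary.

#' Pipeline run configuration
#'
#' @param world a \code{\link{world_config}}.
#' @param align an \code{\link{align_params}}.
#' @param cluster a \code{\link{cluster_config}}.
#' @param flank neighborhood flank (genes per side).
#' @param rbh_genome_pairs number of genome pairs sampled for the
#'   reciprocal-best-hit orthology evaluation (the full quadratic sweep is
#'   unnecessary for the summary statistics).
#' @param output_dir output directory.
#' @param seed global seed; stages derive sub-seeds deterministically. When
#'   NULL, the world config's seed is used.
#' @return an object of class \code{run_config}.
#' @export
run_config <- function(world = world_config(), align = align_params(),
                       cluster = cluster_config(), flank = 5,
                       rbh_genome_pairs = 40, output_dir = "rfahkit_out",
                       seed = NULL) {
  if (is.null(seed)) seed <- world$seed
  world$seed <- seed
  structure(list(world = world, align = align, cluster = cluster,
                 flank = flank, rbh_genome_pairs = rbh_genome_pairs,
                 output_dir = output_dir, seed = seed),
            class = "run_config")
}

#' Write/read a run configuration as YAML
#' @param config a \code{run_config}.
#' @param path file path.
#' @return the path (write) or a \code{run_config} (read).
#' @export
write_run_config <- function(config, path) {
  x <- list(seed = config$seed,
            output_dir = config$output_dir,
            flank = config$flank,
            rbh_genome_pairs = config$rbh_genome_pairs,
            world = config$world[setdiff(names(config$world), "family_specs")],
            align = list(gap_open = config$align$gap_open,
                         gap_extend = config$align$gap_extend,
                         lambda = config$align$lambda, K = config$align$K),
            cluster = unclass(config$cluster))
  x$world$neighborhood_bias <- as.list(config$world$neighborhood_bias)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  wc <- x$world
  wc$neighborhood_bias <- unlist(wc$neighborhood_bias)
  run_config(world = do.call(world_config, wc),
             align = do.call(align_params, x$align %||% list()),
             cluster = do.call(cluster_config, x$cluster %||% list()),
             flank = x$flank %||% 5,
             rbh_genome_pairs = x$rbh_genome_pairs %||% 40,
             output_dir = x$output_dir %||% "rfahkit_out",
             seed = x$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage_log <- function(log, stage, t0, ...) {
  rec <- list(stage = stage,
              seconds = round(as.numeric(Sys.time() - t0, units = "secs"), 3),
              ...)
  c(log, list(rec))
}

#' Run the full pipeline
#'
#' Generates the synthetic world, builds and calibrates the housekeeping and
#' paralog profile models, scans all proteomes, evaluates reciprocal-best-hit
#' orthology on a sample of genome pairs, runs the stepwise clustering of the
#' paralog family, infers the genome, housekeeping and paralog trees with
#' Robinson-Foulds congruence and longest-path sums, annotates functional
#' sites, assembles the presence matrix with completeness screen and operon
#' context, computes the neighborhood COG matrix, and writes everything
#' (plus a summary TSV) under \code{output_dir}.
#'
#' @param config a \code{\link{run_config}}.
#' @return invisibly, a list with the summary and all major in-memory
#'   results.
#' @export
run_all <- function(config = run_config()) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(config$output_dir, 2) != 0)
    stop("output_dir is not writable: ", config$output_dir)
  out <- function(...) file.path(config$output_dir, ...)
  log <- list()

  # ---- stage: world ----------------------------------------------------
  t0 <- Sys.time()
  world <- build_world(config$world)
  write_world(world, out("world"))
  g <- world_genes(world)
  fam <- setNames(g$truth_family, g$gene_id)
  all_seqs <- setNames(g$protein_sequence, g$gene_id)
  log <- stage_log(log, "worldgen", t0, n_genomes = length(world$genomes),
                   n_genes = nrow(g))

  # ---- stage: profile models ------------------------------------------
  t0 <- Sys.time()
  par_ids <- g$gene_id[!is.na(fam) & fam == "paralog"]
  unk_ids <- g$gene_id[!is.na(fam) & fam == "unknown"]
  hk_ids <- g$gene_id[!is.na(fam) & fam == "housekeeping"]
  ctrl_ids <- g$gene_id[!is.na(fam) & fam %in% CONTROL_FAMILIES]
  # curated labels: paralogs are the positives of the paralog model; the
  # housekeeping family, controls and decoys are the curated negatives; the
  # planted "unknown" family is deliberately uncurated
  paralog_model <- build_family_model(
    all_seqs[par_ids], world,
    positives_ids = par_ids,
    negatives_ids = setdiff(g$gene_id, c(par_ids, unk_ids)),
    identity_reduction = 0.80,
    required_sites = PARALOG_SITES,
    params = config$align)
  housekeeping_model <- build_family_model(
    all_seqs[hk_ids], world,
    positives_ids = hk_ids,
    negatives_ids = setdiff(g$gene_id, c(hk_ids, unk_ids)),
    identity_reduction = 0.80,
    required_sites = HOUSEKEEPING_SITES,
    params = config$align)
  control_models <- lapply(CONTROL_FAMILIES, function(f) {
    ids <- g$gene_id[!is.na(fam) & fam == f]
    msa <- msa_from_stack(all_seqs[ids])
    m <- build_profile(msa)
    bits <- score_sequences(m, all_seqs)
    calibrate_cutoffs(m, bits[ids], bits[setdiff(g$gene_id, c(ids, unk_ids))])
  })
  names(control_models) <- CONTROL_FAMILIES
  write_profile(paralog_model, out("paralog_model.txt"))
  write_profile(housekeeping_model, out("housekeeping_model.txt"))
  cutoff_margin <- paralog_model$trusted_cutoff - paralog_model$noise_cutoff
  log <- stage_log(log, "models", t0, cutoff_margin = cutoff_margin)

  # ---- stage: proteome scans ------------------------------------------
  t0 <- Sys.time()
  hits <- c(list(housekeeping = scan_proteomes(housekeeping_model, world),
                 paralog = scan_proteomes(paralog_model, world)),
            lapply(control_models, function(m) scan_proteomes(m, world)))
  for (m in names(hits)) write_tsv(hits[[m]], out(paste0("hits_", m, ".tsv")))
  zones <- setNames(hits$paralog$zone, hits$paralog$gene_id)
  paralog_member_rate <- mean(!is.na(zones[par_ids]) &
                                zones[par_ids] == "member")
  unknown_candidate_rate <-
    mean(!is.na(zones[unk_ids]) & zones[unk_ids] == "candidate")
  log <- stage_log(log, "scan", t0,
                   paralog_member_rate = paralog_member_rate,
                   unknown_candidate_rate = unknown_candidate_rate)

  # ---- stage: RBH orthology -------------------------------------------
  t0 <- Sys.time()
  op <- world$truth$ortholog_pairs
  ids <- names(world$genomes)
  pairs <- t(utils::combn(ids, 2))
  n_pairs <- min(config$rbh_genome_pairs, nrow(pairs))
  sel <- with_seed(substream_seed(config$seed, "rbh_pairs"),
                   pairs[sample.int(nrow(pairs), n_pairs), , drop = FALSE])
  recovered <- 0L; total <- 0L; decoy_pairs <- 0L
  rbh_rows <- list()
  for (k in seq_len(nrow(sel))) {
    rbh <- reciprocal_best_hits(world$genomes[[sel[k, 1]]],
                                world$genomes[[sel[k, 2]]], config$align)
    rbh$genome_a <- sel[k, 1]; rbh$genome_b <- sel[k, 2]
    rbh_rows[[k]] <- rbh
    tp <- op[(op$genome_a == sel[k, 1] & op$genome_b == sel[k, 2]) |
               (op$genome_a == sel[k, 2] & op$genome_b == sel[k, 1]), ]
    key <- paste(pmin(rbh$gene_a, rbh$gene_b), pmax(rbh$gene_a, rbh$gene_b))
    tkey <- paste(pmin(tp$gene_a, tp$gene_b), pmax(tp$gene_a, tp$gene_b))
    recovered <- recovered + sum(tkey %in% key)
    total <- total + length(tkey)
    decoy_pairs <- decoy_pairs +
      sum(is.na(fam[rbh$gene_a]) & is.na(fam[rbh$gene_b]))
  }
  write_tsv(do.call(rbind, rbh_rows), out("rbh_pairs.tsv"))
  ortholog_recall <- if (total > 0) recovered / total else NA_real_
  log <- stage_log(log, "rbh", t0, genome_pairs = n_pairs,
                   ortholog_recall = ortholog_recall,
                   decoy_rbh_pairs = decoy_pairs)

  # ---- stage: clustering ----------------------------------------------
  t0 <- Sys.time()
  cluster_res <- stepwise_cluster(all_seqs[par_ids], config$cluster,
                                  config$align)
  write_clusters(cluster_res, out("clusters.tsv"))
  write_graph_abc(cluster_res$graph, out("similarity_graph.abc"))
  pc <- world$truth$planted_clusters
  cluster_ari <- mclust::adjustedRandIndex(
    cluster_res$clusters[pc$gene_id], pc$cluster)
  log <- stage_log(log, "cluster", t0,
                   n_clusters = length(unique(cluster_res$clusters)),
                   cluster_ari = cluster_ari)

  # ---- stage: trees ----------------------------------------------------
  t0 <- Sys.time()
  markers <- lapply(CONTROL_FAMILIES, function(f) {
    sel_f <- !is.na(fam) & fam == f
    setNames(g$protein_sequence[sel_f], g$genome_id[sel_f])
  })
  genome_tree <- concat_marker_tree(world, markers)
  hk_seqs <- setNames(g$protein_sequence[!is.na(fam) & fam == "housekeeping"],
                      g$genome_id[!is.na(fam) & fam == "housekeeping"])
  hk_tree <- family_tree(hk_seqs, config$align)
  native <- pc[!pc$dup, ]
  native <- native[!duplicated(native$genome_id), ]
  par_tree <- family_tree(setNames(all_seqs[native$gene_id],
                                   native$genome_id), config$align)
  rf_hk <- robinson_foulds(ape::keep.tip(genome_tree, names(hk_seqs)), hk_tree)
  rf_par <- robinson_foulds(ape::keep.tip(genome_tree, native$genome_id),
                            par_tree)
  ape::write.tree(genome_tree, out("genome_tree.nwk"))
  ape::write.tree(hk_tree, out("housekeeping_tree.nwk"))
  ape::write.tree(par_tree, out("paralog_tree.nwk"))
  rf_table <- data.frame(
    comparison = c("genome_vs_housekeeping", "genome_vs_paralog"),
    rf_raw = c(rf_hk["raw"], rf_par["raw"]),
    rf_normalized = c(rf_hk["normalized"], rf_par["normalized"]))
  write_tsv(rf_table, out("rf_table.tsv"))
  path_sums <- c(housekeeping = longest_path_sum(hk_tree),
                 paralog = longest_path_sum(par_tree))
  log <- stage_log(log, "trees", t0, rf_housekeeping = unname(rf_hk["raw"]),
                   rf_paralog = unname(rf_par["raw"]),
                   path_sum_paralog = unname(path_sums["paralog"]),
                   path_sum_housekeeping = unname(path_sums["housekeeping"]))

  # ---- stage: functional sites ----------------------------------------
  t0 <- Sys.time()
  nusg_like <- c(par_ids, unk_ids, hk_ids)
  site_msa <- msa_from_stack(all_seqs[nusg_like])
  scheme <- default_site_scheme(par_ids[1])
  site_table <- annotate_states(site_msa, scheme)
  write_tsv(site_table, out("site_states.tsv"))
  groups <- list(paralog = par_ids, unknown = unk_ids, housekeeping = hk_ids)
  site_freqs <- clade_state_frequencies(site_table, groups)
  write_tsv(site_freqs, out("site_frequencies.tsv"))
  log <- stage_log(log, "sites", t0)

  # ---- stage: phyletic profiling --------------------------------------
  t0 <- Sys.time()
  pm <- presence_matrix(hits, world)
  write_tsv(data.frame(genome_id = rownames(pm), as.data.frame(pm),
                       check.names = FALSE), out("presence_matrix.tsv"))
  taxonomy <- setNames(world$truth$clades, names(world$truth$clades))
  pct <- percent_hits(pm, taxonomy, "paralog", min_genomes = 10)
  reduced_flagged <- completeness_screen(pm, "housekeeping", CONTROL_FAMILIES)
  loci <- do.call(rbind, lapply(world$genomes, function(gn) {
    lc <- operon_context(gn, c("control_secE", "housekeeping",
                               "control_rplK", "control_rplA"),
                         optional_slot = 2)
    if (nrow(lc) > 0) lc$genome_id <- gn$genome_id
    lc
  }))
  write_tsv(loci, out("operon_loci.tsv"))
  completeness_ok <-
    setequal(reduced_flagged, world$truth$reduced_genomes)
  log <- stage_log(log, "profiling", t0,
                   n_flagged_reduced = length(reduced_flagged),
                   completeness_matches_truth = completeness_ok)

  # ---- stage: neighborhoods -------------------------------------------
  t0 <- Sys.time()
  cm <- cog_matrix(setNames(pc$cluster, pc$gene_id), world, config$flank)
  write_cog_matrix(cm, out("cog_matrix.tsv"))
  pctm <- cog_percentages(cm)
  argmax <- colnames(pctm)[apply(pctm, 1, which.max)]
  names(argmax) <- rownames(pctm)
  bias <- config$world$neighborhood_bias
  bias_recovery <- mean(argmax[names(bias)] == bias)
  log <- stage_log(log, "neighborhood", t0, bias_recovery = bias_recovery)

  # ---- summary ---------------------------------------------------------
  summary <- list(
    cluster_ari = cluster_ari,
    ortholog_recall = ortholog_recall,
    decoy_rbh_pairs = decoy_pairs,
    trusted_cutoff = paralog_model$trusted_cutoff,
    noise_cutoff = paralog_model$noise_cutoff,
    cutoff_margin = cutoff_margin,
    paralog_member_rate = paralog_member_rate,
    unknown_candidate_rate = unknown_candidate_rate,
    rf_housekeeping = unname(rf_hk["raw"]),
    rf_paralog = unname(rf_par["raw"]),
    path_sum_paralog = unname(path_sums["paralog"]),
    path_sum_housekeeping = unname(path_sums["housekeeping"]),
    neighborhood_bias_recovery = bias_recovery)
  sdf <- data.frame(metric = names(summary),
                    value = vapply(summary, function(x)
                      format(signif(as.numeric(x), 6)), character(1)))
  write_tsv(sdf, out("summary.tsv"))
  logdf <- do.call(rbind, lapply(log, function(r)
    data.frame(stage = r$stage, seconds = r$seconds,
               details = paste(names(r)[-(1:2)], unlist(r[-(1:2)]),
                               sep = "=", collapse = ";"))))
  write_tsv(logdf, out("stages.tsv"))

  invisible(list(summary = summary, world = world,
                 paralog_model = paralog_model,
                 housekeeping_model = housekeeping_model,
                 hits = hits, clusters = cluster_res,
                 trees = list(genome = genome_tree, housekeeping = hk_tree,
                              paralog = par_tree),
                 site_table = site_table, site_frequencies = site_freqs,
                 presence = pm, flagged_reduced = reduced_flagged,
                 cog = cm, log = log))
}
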