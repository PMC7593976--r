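# Synthetic genome worlds with planted evolutionary structure.
#
# The generator emulates the shape of the real study inputs — a large set of
# representative genomes carrying a ubiquitous housekeeping NusG-like family
# inside a conserved secE-nusG-rplK-rplA operon, a patchy RfaH-like paralog
# family with planted subfamilies, duplications and horizontal transfers, an
# intermediate-divergence "unknown" family, seven single-copy control marker
# families, per-subfamily gene-neighborhood COG biases, and severely reduced
# genomes lacking the housekeeping gene — together with the ground-truth
# tables every downstream stage is scored against.

# RfaH-like planted functional residues (E. coli numbering) and the divergent
# residues carried by the housekeeping family at the same positions
PARALOG_SITES <- c("10" = "K", "48" = "E", "56" = "F", "73" = "R",
                   "81" = "F", "93" = "I", "130" = "F", "145" = "L",
                   "146" = "I", "147" = "N")
HOUSEKEEPING_SITES <- c("10" = "F", "48" = "K", "56" = "L", "73" = "D",
                        "81" = "G", "93" = "D", "130" = "A", "145" = "G",
                        "146" = "E", "147" = "W")

COG_LETTERS <- c("J", "K", "L", "D", "O", "M", "N", "P", "T", "C",
                 "G", "E", "F", "H", "I", "Q", "R", "S", "U", "V")

CONTROL_FAMILIES <- c("control_secE", "control_rplK", "control_rplA",
                      "control_recA", "control_rplE", "control_rplF",
                      "control_rpsB")

#' Specification of one planted protein family
#'
#' @param name family label.
#' @param ancestor_length ancestor length in residues (>= 50).
#' @param substitution_rate_multiplier rate multiplier (>= 0) applied on top
#'   of species-tree branch lengths.
#' @param presence_fraction fraction of genomes carrying the family.
#' @param site_states named character vector: 1-based ancestor position ->
#'   required residue, held fixed in every tip.
#' @return an object of class \code{family_spec}.
#' @export
family_spec <- function(name, ancestor_length = 300,
                        substitution_rate_multiplier = 1,
                        presence_fraction = 1, site_states = NULL) {
  stopifnot(ancestor_length >= 50,
            presence_fraction >= 0, presence_fraction <= 1,
            substitution_rate_multiplier >= 0)
  if (!is.null(site_states)) {
    pos <- as.integer(names(site_states))
    if (any(pos < 1) || any(pos > ancestor_length))
      stop("site_states positions must lie within the ancestor")
  }
  structure(list(name = name, ancestor_length = ancestor_length,
                 rate = substitution_rate_multiplier,
                 presence_fraction = presence_fraction,
                 site_states = site_states),
            class = "family_spec")
}

#' Configuration of a synthetic genome world
#'
#' The defaults are the package's reference study conditions: 40 genomes in 4
#' clades, a ubiquitous housekeeping family, a paralog family present in 60%
#' of genomes split into 3 subfamilies with 3 horizontal transfers and 2
#' in-genome duplications, an unknown family of intermediate divergence in 5
#' genomes, 7 single-copy controls, 30 decoy proteins per genome and 2
#' reduced genomes lacking the housekeeping gene.
#'
#' @param n_genomes number of genomes (>= 4).
#' @param n_clades number of clades the species tree is cut into.
#' @param birth_rate pure-birth speciation rate for the species tree.
#' @param tree_height root-to-tip height, substitutions/site at rate 1.
#' @param n_subfamilies paralog subfamilies (planted clusters).
#' @param subfamily_height crown height (substitutions/site before the rate
#'   multiplier) of each paralog subfamily radiation; smaller than the clade
#'   crown because the paralog radiated after its host clades.
#' @param paralog_presence fraction of genomes carrying the paralog.
#' @param unknown_genomes genomes carrying the unknown family.
#' @param n_hgt_events planted horizontal transfers of the paralog.
#' @param n_duplications planted in-genome paralog duplications.
#' @param n_reduced_genomes genomes lacking the housekeeping family.
#' @param decoys_per_genome unrelated decoy proteins per genome.
#' @param neighborhood_bias named character vector cluster label -> enriched
#'   COG category for the paralog gene neighborhoods.
#' @param bias_strength probability a neighbor decoy adopts the bias category.
#' @param seed integer seed; fully determines the world.
#' @return an object of class \code{world_config}.
#' @export
world_config <- function(n_genomes = 40, n_clades = 4, birth_rate = 1,
                         tree_height = 0.3, n_subfamilies = 3,
                         subfamily_height = 0.08,
                         paralog_presence = 0.6, unknown_genomes = 5,
                         n_hgt_events = 3, n_duplications = 2,
                         n_reduced_genomes = 2, decoys_per_genome = 30,
                         neighborhood_bias = c(CL1 = "M", CL2 = "G", CL3 = "T"),
                         bias_strength = 0.6, seed = 1) {
  stopifnot(n_genomes >= 4, n_reduced_genomes < n_genomes,
            n_clades >= 1, n_clades <= n_genomes,
            n_subfamilies >= 1, n_subfamilies <= n_clades,
            length(neighborhood_bias) == n_subfamilies)
  if (!identical(sort(names(neighborhood_bias)),
                 sort(paste0("CL", seq_len(n_subfamilies)))))
    stop("neighborhood_bias must name clusters CL1..CLk for k subfamilies")
  fams <- list(
    housekeeping = family_spec("housekeeping", 300, 1, 1,
                               HOUSEKEEPING_SITES),
    paralog = family_spec("paralog", 300, 3, paralog_presence,
                          PARALOG_SITES),
    unknown = family_spec("unknown", 300, 1.5, unknown_genomes / n_genomes)
  )
  for (cf in CONTROL_FAMILIES) fams[[cf]] <- family_spec(cf, 300, 1, 1)
  structure(list(n_genomes = n_genomes, n_clades = n_clades,
                 birth_rate = birth_rate, tree_height = tree_height,
                 n_subfamilies = n_subfamilies,
                 subfamily_height = subfamily_height,
                 paralog_presence = paralog_presence,
                 unknown_genomes = unknown_genomes,
                 n_hgt_events = n_hgt_events,
                 n_duplications = n_duplications,
                 n_reduced_genomes = n_reduced_genomes,
                 decoys_per_genome = decoys_per_genome,
                 neighborhood_bias = neighborhood_bias,
                 bias_strength = bias_strength,
                 family_specs = fams, seed = seed),
            class = "world_config")
}

#' Sample a pure-birth species tree
#'
#' Draws a pure-birth (Yule) tree with \code{n_taxa} leaves labelled
#' \code{genome_1..genome_n}, rescales it to the requested height and applies
#' a minimum branch length so every split carries recoverable signal in
#' family alignments of a few hundred columns. The tree is therefore
#' ultrametric in expectation but not exactly after flooring.
#'
#' @param n_taxa number of leaves (>= 3).
#' @param seed integer seed.
#' @param birth_rate speciation rate.
#' @param height target root-to-tip height (substitutions/site at rate 1).
#' @param min_branch minimum branch length after rescaling.
#' @return an \code{ape::phylo} tree with positive branch lengths.
#' @export
sample_species_tree <- function(n_taxa, seed, birth_rate = 1, height = 0.3,
                                min_branch = 0.05) {
  if (n_taxa < 3) stop("n_taxa must be at least 3")
  tr <- with_seed(substream_seed(seed, "species_tree"), {
    ape::rphylo(n_taxa, birth = birth_rate, death = 0)
  })
  tr$tip.label <- paste0("genome_", seq_len(n_taxa))
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / depth * height
  tr$edge.length[tr$edge.length < min_branch] <- min_branch
  tr
}

# cut a rooted tree into k clades by slicing at the time where exactly k
# lineages exist (repeatedly split the shallowest internal lineage);
# returns genome -> clade label map, labels ordered by smallest tip number
clade_assignment <- function(tree, k) {
  n <- length(tree$tip.label)
  if (k == 1) return(setNames(rep("clade_1", n), tree$tip.label))
  depths <- ape::node.depth.edgelength(tree)
  groups <- n + 1L  # start from the root
  while (length(groups) < k) {
    internal <- groups[groups > n]
    if (length(internal) == 0) break
    split_node <- internal[which.min(depths[internal])]
    children <- tree$edge[tree$edge[, 1] == split_node, 2]
    groups <- c(setdiff(groups, split_node), children)
  }
  tips_of <- function(v) {
    if (v <= n) tree$tip.label[v] else ape::extract.clade(tree, v)$tip.label
  }
  tip_sets <- lapply(groups, tips_of)
  ord <- order(vapply(tip_sets, function(ts)
    min(as.integer(sub("genome_", "", ts))), numeric(1)))
  res <- setNames(rep(NA_character_, n), tree$tip.label)
  for (i in seq_along(ord)) res[tip_sets[[ord[i]]]] <- paste0("clade_", i)
  res
}

# mutate a sequence by an expected distance d (substitutions/site), keeping
# fixed_pos (integer positions) untouched
mutate_seq <- function(chars, d, fixed_pos = integer(0)) {
  n <- length(chars)
  nev <- rpois(n, d)
  mut <- which(nev > 0)
  mut <- setdiff(mut, fixed_pos)
  for (p in mut) {
    for (k in seq_len(nev[p])) {
      alt <- AA_ALPHABET[AA_ALPHABET != chars[p]]
      chars[p] <- alt[sample.int(19L, 1L)]
    }
  }
  chars
}

# natural amino-acid frequencies (Robinson & Robinson), the composition the
# Karlin-Altschul constants are calibrated for; used for all random sequence
# draws so analytic E-values of chance alignments behave like BLAST's
ROBINSON_FREQS <- c(A = 0.0780, R = 0.0512, N = 0.0448, D = 0.0536,
                    C = 0.0192, Q = 0.0426, E = 0.0629, G = 0.0738,
                    H = 0.0219, I = 0.0514, L = 0.0901, K = 0.0574,
                    M = 0.0224, F = 0.0386, P = 0.0520, S = 0.0712,
                    T = 0.0584, W = 0.0132, Y = 0.0321, V = 0.0644)

random_seq <- function(len, freqs = ROBINSON_FREQS[AA_ALPHABET]) {
  paste(sample(AA_ALPHABET, len, replace = TRUE, prob = freqs), collapse = "")
}

#' Evolve a protein family along a tree
#'
#' Simple per-site replacement process: on each branch the number of
#' replacement events per site is Poisson with mean branch length x rate
#' multiplier, each event substituting one of the 19 alternative residues
#' uniformly. No indels are introduced, so the family alignment is the plain
#' stack of tip sequences. Positions in \code{site_states} are held fixed at
#' the required residue in every tip.
#'
#' @param ancestor ancestor protein sequence (single string).
#' @param tree an \code{ape::phylo} tree whose tips receive sequences.
#' @param rate_multiplier non-negative rate scaling.
#' @param site_states named character vector position -> required residue.
#' @param seed integer seed.
#' @return named character vector of tip sequences.
#' @export
evolve_family <- function(ancestor, tree, rate_multiplier = 1,
                          site_states = NULL, seed = 1) {
  stopifnot(nchar(ancestor) > 0)
  chars <- strsplit(ancestor, "")[[1]]
  fixed <- integer(0)
  if (!is.null(site_states) && length(site_states) > 0) {
    fixed <- as.integer(names(site_states))
    if (any(fixed < 1) || any(fixed > length(chars)))
      stop("site_states position out of range")
    chars[fixed] <- unname(site_states)
  }
  n <- length(tree$tip.label)
  root <- n + 1L
  seqs <- vector("list", n + tree$Nnode)
  seqs[[root]] <- chars
  # preorder edge traversal; one sub-stream per child node label
  ord <- reorder(tree, "cladewise")$edge
  lens <- reorder(tree, "cladewise")$edge.length
  for (k in seq_len(nrow(ord))) {
    par <- ord[k, 1]; child <- ord[k, 2]
    lab <- if (child <= n) tree$tip.label[child] else paste0("node_", child)
    sub <- substream_seed(seed, "evolve", lab)
    seqs[[child]] <- with_seed(sub, {
      mutate_seq(seqs[[par]], lens[k] * rate_multiplier, fixed)
    })
  }
  out <- vapply(seq_len(n), function(i) paste(seqs[[i]], collapse = ""),
                character(1))
  setNames(out, tree$tip.label)
}

#' Build a synthetic genome world
#'
#' Generates genomes and truth tables under a \code{\link{world_config}}:
#' the housekeeping family sits in every non-reduced genome inside the
#' conserved operon context control_secE -> housekeeping -> control_rplK ->
#' control_rplA (consecutive indices, same contig and strand); the paralog
#' family is placed in a fraction of genomes with planted subfamilies,
#' horizontal transfers across clades and in-genome duplications; paralog
#' neighborhoods are enriched for a subfamily-specific COG category; reduced
#' genomes lack the housekeeping family but keep all controls.
#'
#' @param config a \code{\link{world_config}}.
#' @return a list of class \code{genome_world} with elements \code{genomes}
#'   (list of \code{genome} objects), \code{truth} (truth tables),
#'   \code{tree} (species tree) and \code{config}.
#' @export
build_world <- function(config) {
  stopifnot(inherits(config, "world_config"))
  seed <- config$seed
  n <- config$n_genomes
  tree <- sample_species_tree(n, seed, config$birth_rate, config$tree_height)
  clades <- clade_assignment(tree, config$n_clades)
  genome_ids <- tree$tip.label

  # ---- ancestors ------------------------------------------------------
  # one NusG-superfamily root; the paralog ancestor is a distant homolog of
  # the housekeeping ancestor, subfamily ancestors radiate from the paralog
  # ancestor, the unknown ancestor sits in between
  anc <- with_seed(substream_seed(seed, "ancestors"), {
    hk_chars <- strsplit(random_seq(300), "")[[1]]
    hk_fixed <- as.integer(names(HOUSEKEEPING_SITES))
    hk_chars[hk_fixed] <- unname(HOUSEKEEPING_SITES)
    par_chars <- mutate_seq(hk_chars, 1.6)
    par_fixed <- as.integer(names(PARALOG_SITES))
    par_chars[par_fixed] <- unname(PARALOG_SITES)
    sub_anc <- lapply(seq_len(config$n_subfamilies), function(k) {
      ch <- mutate_seq(par_chars, 0.6, par_fixed)
      ch[par_fixed] <- unname(PARALOG_SITES)
      ch
    })
    unk_chars <- mutate_seq(par_chars, 0.7)
    ctrl <- lapply(CONTROL_FAMILIES, function(f) strsplit(random_seq(300), "")[[1]])
    names(ctrl) <- CONTROL_FAMILIES
    list(hk = hk_chars, par = par_chars, sub = sub_anc, unk = unk_chars,
         ctrl = ctrl)
  })

  # ---- vertically inherited families ----------------------------------
  hk_seqs <- evolve_family(paste(anc$hk, collapse = ""), tree, 1,
                           HOUSEKEEPING_SITES,
                           substream_seed(seed, "fam", "housekeeping"))
  ctrl_seqs <- lapply(CONTROL_FAMILIES, function(f)
    evolve_family(paste(anc$ctrl[[f]], collapse = ""), tree, 1, NULL,
                  substream_seed(seed, "fam", f)))
  names(ctrl_seqs) <- CONTROL_FAMILIES

  # ---- paralog subfamilies -------------------------------------------
  # subfamily k is native to clade_k; carriers drawn per clade
  clade_of <- split(names(clades), clades)
  par_rate <- config$family_specs$paralog$rate
  n_carriers <- round(config$paralog_presence * n)
  carriers <- with_seed(substream_seed(seed, "paralog_carriers"), {
    native_clades <- paste0("clade_", seq_len(config$n_subfamilies))
    pool <- unlist(clade_of[native_clades], use.names = FALSE)
    sort(sample(pool, min(n_carriers, length(pool))))
  })
  par_seq_of <- list()   # genome -> sequence (native copies)
  subfam_of <- character(0)
  for (k in seq_len(config$n_subfamilies)) {
    cl <- paste0("clade_", k)
    members <- intersect(clade_of[[cl]], carriers)
    if (length(members) == 0) next
    sub_tree <- if (length(members) >= 2) {
      st <- ape::keep.tip(tree, members)
      # the subfamily radiated after its host clade: rescale the induced
      # subtree to the configured subfamily crown height
      st$edge.length <- st$edge.length /
        max(ape::node.depth.edgelength(st)) * config$subfamily_height
      st
    } else NULL
    anc_seq <- paste(anc$sub[[k]], collapse = "")
    if (is.null(sub_tree)) {
      s <- with_seed(substream_seed(seed, "subfam", cl, members), {
        paste(mutate_seq(anc$sub[[k]], config$subfamily_height * par_rate,
                         as.integer(names(PARALOG_SITES))), collapse = "")
      })
      tips <- setNames(s, members)
    } else {
      tips <- evolve_family(anc_seq, sub_tree, par_rate, PARALOG_SITES,
                            substream_seed(seed, "subfam", cl))
    }
    for (g in names(tips)) {
      par_seq_of[[g]] <- tips[[g]]
      subfam_of[g] <- paste0("CL", k)
    }
  }

  # ---- HGT events ------------------------------------------------------
  # recipient genomes outside the donor clade receive a donor-lineage copy
  hgt <- with_seed(substream_seed(seed, "hgt"), {
    non_carriers <- setdiff(genome_ids, carriers)
    if (config$n_hgt_events > length(non_carriers))
      stop("infeasible config: more HGT events than available recipients")
    recips <- character(0)
    events <- list()
    for (i in seq_len(config$n_hgt_events)) {
      # draw a donor subfamily that still has a recipient outside its clade
      donor_order <- sample(seq_len(config$n_subfamilies))
      donor <- NA_integer_; ok <- character(0)
      for (d in donor_order) {
        cand <- setdiff(non_carriers, recips)
        cand <- cand[clades[cand] != paste0("clade_", d)]
        if (length(cand) > 0) { donor <- d; ok <- cand; break }
      }
      if (is.na(donor))
        stop("infeasible config: no HGT recipient outside any donor clade")
      donor_clade <- paste0("clade_", donor)
      r <- if (length(ok) == 1) ok else sample(ok, 1)
      recips <- c(recips, r)
      seq_ <- paste(mutate_seq(anc$sub[[donor]],
                               config$subfamily_height * par_rate,
                               as.integer(names(PARALOG_SITES))),
                    collapse = "")
      events[[i]] <- list(recipient = r, donor_clade = donor_clade,
                          subfam = paste0("CL", donor), seq = seq_)
    }
    events
  })

  # ---- duplications ----------------------------------------------------
  dups <- with_seed(substream_seed(seed, "dup"), {
    if (config$n_duplications > length(carriers))
      stop("infeasible config: more duplications than paralog carriers")
    hosts <- sample(carriers, config$n_duplications)
    lapply(hosts, function(g) {
      ch <- strsplit(par_seq_of[[g]], "")[[1]]
      list(genome = g, subfam = subfam_of[[g]],
           seq = paste(mutate_seq(ch, 0.05,
                                  as.integer(names(PARALOG_SITES))),
                       collapse = ""))
    })
  })

  # ---- unknown family --------------------------------------------------
  unk <- with_seed(substream_seed(seed, "unknown"), {
    hosts <- sort(sample(genome_ids, config$unknown_genomes))
    seqs <- lapply(hosts, function(g)
      paste(mutate_seq(anc$unk, 0.15), collapse = ""))
    setNames(seqs, hosts)
  })

  # ---- reduced genomes -------------------------------------------------
  reduced <- with_seed(substream_seed(seed, "reduced"), {
    pool <- setdiff(genome_ids, c(carriers,
                                  vapply(hgt, `[[`, character(1), "recipient")))
    sort(sample(pool, config$n_reduced_genomes))
  })

  # ---- assemble genomes ------------------------------------------------
  genomes <- list()
  fam_rows <- list()
  cluster_rows <- list()
  for (g in genome_ids) {
    gs <- substream_seed(seed, "genome", g)
    entries <- list()  # each: list(seq, cog, family or NA, block id)
    add <- function(entries, seq, cog, family) {
      entries[[length(entries) + 1L]] <- list(seq = seq, cog = cog,
                                              family = family)
      entries
    }
    entries <- with_seed(gs, {
      e <- list()
      for (d in seq_len(config$decoys_per_genome)) {
        len <- sample(80:300, 1)
        cog <- if (runif(1) < 0.1) "-" else sample(COG_LETTERS, 1)
        e <- add(e, random_seq(len), cog, NA_character_)
      }
      e
    })
    # blocks of family genes; each block stays contiguous and is dropped
    # into a gap between decoys, so blocks can never split each other
    operon <- list(
      list(seq = ctrl_seqs$control_secE[[g]], cog = "U", family = "control_secE"),
      if (!(g %in% reduced))
        list(seq = hk_seqs[[g]], cog = "K", family = "housekeeping"),
      list(seq = ctrl_seqs$control_rplK[[g]], cog = "J", family = "control_rplK"),
      list(seq = ctrl_seqs$control_rplA[[g]], cog = "J", family = "control_rplA"))
    operon <- operon[!vapply(operon, is.null, logical(1))]
    other_ctrl <- setdiff(CONTROL_FAMILIES,
                          c("control_secE", "control_rplK", "control_rplA"))
    ctrl_cog <- c(control_recA = "L", control_rplE = "J", control_rplF = "J",
                  control_rpsB = "J")
    blocks <- list(operon,
                   lapply(other_ctrl, function(f)
                     list(seq = ctrl_seqs[[f]][[g]], cog = ctrl_cog[[f]],
                          family = f)))
    if (g %in% names(par_seq_of))
      blocks <- c(blocks, list(list(list(seq = par_seq_of[[g]], cog = "K",
                                         family = "paralog",
                                         subfam = subfam_of[[g]]))))
    for (ev in hgt) if (ev$recipient == g)
      blocks <- c(blocks, list(list(list(seq = ev$seq, cog = "K",
                                         family = "paralog",
                                         subfam = ev$subfam, hgt = TRUE))))
    for (dp in dups) if (dp$genome == g)
      blocks <- c(blocks, list(list(list(seq = dp$seq, cog = "K",
                                         family = "paralog",
                                         subfam = dp$subfam, dup = TRUE))))
    if (g %in% names(unk))
      blocks <- c(blocks, list(list(list(seq = unk[[g]], cog = "K",
                                         family = "unknown"))))
    # one decoy-gap slot per block (slots 0..n_decoys; ties keep block order)
    slots <- with_seed(substream_seed(seed, "layout", g), {
      sample.int(length(entries) + 1L, length(blocks), replace = TRUE) - 1L
    })
    seq_entries <- list()
    for (s in 0:length(entries)) {
      for (bi in which(slots == s))
        seq_entries <- c(seq_entries, blocks[[bi]])
      if (s < length(entries))
        seq_entries <- c(seq_entries, entries[s + 1L])
    }

    # neighborhood bias: flanking decoys of each paralog copy adopt the
    # subfamily's COG category with probability bias_strength
    fams <- vapply(seq_entries, function(x)
      if (is.na(x$family)) "" else x$family, character(1))
    par_idx <- which(fams == "paralog")
    if (length(par_idx) > 0) {
      seq_entries <- with_seed(substream_seed(seed, "bias", g), {
        for (pi in par_idx) {
          cl <- seq_entries[[pi]]$subfam
          bias_cog <- config$neighborhood_bias[[cl]]
          win <- setdiff(max(1, pi - 5):min(length(seq_entries), pi + 5), pi)
          for (w in win) {
            if (!is.na(seq_entries[[w]]$family)) next
            if (runif(1) < config$bias_strength)
              seq_entries[[w]]$cog <- bias_cog
          }
        }
        seq_entries
      })
    }

    strands <- with_seed(substream_seed(seed, "strand", g), {
      s <- sample(c("+", "-"), length(seq_entries), replace = TRUE)
      s
    })
    # operon genes share one strand
    op_idx <- which(vapply(seq_entries, function(x)
      !is.na(x$family) && x$family %in% c("control_secE", "housekeeping",
                                          "control_rplK", "control_rplA"),
      logical(1)))
    strands[op_idx] <- "+"

    gnum <- sub("genome_", "", g)
    ids <- sprintf("g%s_%04d", gnum, seq_along(seq_entries))
    genes <- data.frame(
      gene_id = ids, contig_id = "c1", index = seq_along(seq_entries) - 1L,
      strand = strands,
      cog_category = vapply(seq_entries, `[[`, character(1), "cog"),
      truth_family = vapply(seq_entries, function(x) x$family, character(1)),
      protein_sequence = vapply(seq_entries, `[[`, character(1), "seq"),
      stringsAsFactors = FALSE)
    genomes[[g]] <- structure(list(genome_id = g,
                                   lineage = c(class = clades[[g]],
                                               family = clades[[g]]),
                                   genes = genes),
                              class = "genome")
    for (i in seq_along(seq_entries)) {
      x <- seq_entries[[i]]
      if (!is.na(x$family)) {
        fam_rows[[length(fam_rows) + 1L]] <-
          data.frame(gene_id = ids[i], family = x$family,
                     genome_id = g, stringsAsFactors = FALSE)
        if (identical(x$family, "paralog"))
          cluster_rows[[length(cluster_rows) + 1L]] <-
            data.frame(gene_id = ids[i], cluster = x$subfam,
                       genome_id = g,
                       hgt = isTRUE(x$hgt), dup = isTRUE(x$dup),
                       stringsAsFactors = FALSE)
      }
    }
  }

  family_membership <- do.call(rbind, fam_rows)
  planted_clusters <- do.call(rbind, cluster_rows)

  # ---- truth: ortholog pairs (single-copy vertical families) -----------
  single_copy <- c("housekeeping", CONTROL_FAMILIES)
  fam_genes <- split(family_membership, family_membership$family)
  pair_rows <- list()
  for (f in single_copy) {
    fg <- fam_genes[[f]]
    if (is.null(fg) || nrow(fg) < 2) next
    cmb <- utils::combn(seq_len(nrow(fg)), 2)
    pair_rows[[f]] <- data.frame(
      gene_a = fg$gene_id[cmb[1, ]], gene_b = fg$gene_id[cmb[2, ]],
      genome_a = fg$genome_id[cmb[1, ]], genome_b = fg$genome_id[cmb[2, ]],
      family = f, stringsAsFactors = FALSE)
  }
  ortholog_pairs <- do.call(rbind, pair_rows)
  rownames(ortholog_pairs) <- NULL

  hgt_rows <- do.call(rbind, lapply(hgt, function(ev) {
    gid <- planted_clusters$gene_id[planted_clusters$genome_id == ev$recipient &
                                      planted_clusters$hgt]
    data.frame(gene_id = gid[1], donor_clade = ev$donor_clade,
               recipient_clade = clades[[ev$recipient]],
               recipient_genome = ev$recipient, stringsAsFactors = FALSE)
  }))

  truth <- list(family_membership = family_membership,
                ortholog_pairs = ortholog_pairs,
                hgt_events = hgt_rows,
                planted_clusters = planted_clusters,
                species_tree = tree,
                clades = clades,
                reduced_genomes = reduced,
                carriers = carriers)
  structure(list(genomes = genomes, truth = truth, tree = tree,
                 config = config),
            class = "genome_world")
}

#' Write a genome world to disk
#'
#' Emits one protein FASTA per genome (headers \code{gene_id|genome_id|index}),
#' a world-level gene table TSV, truth tables as TSV and the species tree as
#' Newick. Outputs are byte-identical for identical configs.
#'
#' @param world a \code{genome_world}.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (g in names(world$genomes)) {
    gn <- world$genomes[[g]]
    seqs <- setNames(gn$genes$protein_sequence,
                     paste(gn$genes$gene_id, g, gn$genes$index, sep = "|"))
    write_fasta(seqs, file.path(dir, paste0(g, ".faa")))
  }
  gene_tab <- do.call(rbind, lapply(world$genomes, function(gn)
    data.frame(genome_id = gn$genome_id, contig_id = gn$genes$contig_id,
               index = gn$genes$index, gene_id = gn$genes$gene_id,
               strand = gn$genes$strand,
               cog_category = gn$genes$cog_category,
               stringsAsFactors = FALSE)))
  rownames(gene_tab) <- NULL
  write_tsv(gene_tab, file.path(dir, "gene_table.tsv"))
  write_tsv(world$truth$family_membership, file.path(dir, "truth_families.tsv"))
  write_tsv(world$truth$ortholog_pairs, file.path(dir, "truth_orthologs.tsv"))
  write_tsv(world$truth$planted_clusters, file.path(dir, "truth_clusters.tsv"))
  if (!is.null(world$truth$hgt_events))
    write_tsv(world$truth$hgt_events, file.path(dir, "truth_hgt.tsv"))
  ape::write.tree(world$tree, file.path(dir, "species_tree.nwk"))
  tax <- data.frame(genome_id = names(world$truth$clades),
                    taxon = paste(world$truth$clades,
                                  world$truth$clades, sep = ";"),
                    stringsAsFactors = FALSE)
  write_tsv(tax, file.path(dir, "taxonomy.tsv"))
  invisible(dir)
}

# convenience accessors used across modules -------------------------------

#' All genes of a world as one data frame
#' @param world a \code{genome_world}.
#' @return data frame with one row per gene, including genome id.
#' @export
world_genes <- function(world) {
  out <- do.call(rbind, lapply(world$genomes, function(gn) {
    df <- gn$genes
    df$genome_id <- gn$genome_id
    df
  }))
  rownames(out) <- NULL
  out
}

# named character vector of sequences for a family, by truth label
family_sequences <- function(world, family) {
  g <- world_genes(world)
  g <- g[!is.na(g$truth_family) & g$truth_family == family, ]
  setNames(g$protein_sequence, g$gene_id)
}
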