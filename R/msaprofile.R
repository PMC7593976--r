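# Center-star multiple alignment, profile-model construction with
# match/insert/delete states, glocal Viterbi bit scoring, trusted/noise
# cutoff calibration and proteome scanning — the package's reimplementation
# of the profile-based RfaH model-building workflow.

#' Center-star multiple sequence alignment
#'
#' The center is the sequence maximising the summed pairwise global alignment
#' scores against all others (ties broken by lexicographically smallest id);
#' every other sequence is aligned to the center and merged under "once a
#' gap, always a gap".
#'
#' @param seqs named character vector of >= 2 protein sequences.
#' @param params an \code{\link{align_params}}.
#' @return an object of class \code{msa}: list with \code{ids},
#'   \code{rows} (equal-width aligned strings) and \code{width}.
#' @export
center_star_msa <- function(seqs, params = align_params()) {
  if (length(seqs) < 2) stop("center-star MSA needs at least 2 sequences")
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  ids <- names(seqs)
  n <- length(seqs)
  # summed pairwise global scores; C++ batch on the global kernel
  enc <- lapply(seqs, encode_seq, alphabet = params$alphabet)
  score <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- .cpp_global_align(enc[[i]], enc[[j]], params$matrix,
                           params$gap_open, params$gap_extend)$score
    score[i, j] <- s; score[j, i] <- s
  }
  tot <- rowSums(score)
  center <- which(tot == max(tot))
  center <- center[order(ids[center])][1]

  # master gap pattern of the center; rows stored as character vectors
  master <- strsplit(seqs[[center]], "")[[1]]
  rows <- list()
  rows[[ids[center]]] <- master
  for (k in seq_len(n)[-center]) {
    aln <- global_align(seqs[[center]], seqs[[k]], params)
    ac <- strsplit(aln$aligned_query, "")[[1]]    # center with new gaps
    ak <- strsplit(aln$aligned_subject, "")[[1]]
    # map the freshly aligned center onto the running master pattern:
    # walk both, inserting gaps on whichever side lacks them
    new_master <- character(0)
    new_rows <- lapply(rows, function(r) character(0))
    new_k <- character(0)
    i <- 1L; j <- 1L  # i over master, j over ac/ak
    nm <- length(master); na <- length(ac)
    while (i <= nm || j <= na) {
      mi <- if (i <= nm) master[i] else NULL
      aj <- if (j <= na) ac[j] else NULL
      if (!is.null(mi) && mi == "-" && (is.null(aj) || aj != "-")) {
        # master has a gap the new alignment lacks: pad the new row
        new_master <- c(new_master, "-")
        for (id in names(rows)) new_rows[[id]] <- c(new_rows[[id]], rows[[id]][i])
        new_k <- c(new_k, "-")
        i <- i + 1L
      } else if (!is.null(aj) && aj == "-" && (is.null(mi) || mi != "-")) {
        # new alignment opened a gap in the center: pad all existing rows
        new_master <- c(new_master, "-")
        for (id in names(rows)) new_rows[[id]] <- c(new_rows[[id]], "-")
        new_k <- c(new_k, ak[j])
        j <- j + 1L
      } else {
        new_master <- c(new_master, mi)
        for (id in names(rows)) new_rows[[id]] <- c(new_rows[[id]], rows[[id]][i])
        new_k <- c(new_k, ak[j])
        i <- i + 1L; j <- j + 1L
      }
    }
    master <- new_master
    rows <- new_rows
    rows[[ids[k]]] <- new_k
  }
  rows <- rows[ids]  # restore input order
  structure(list(ids = ids,
                 rows = vapply(rows, paste, character(1), collapse = ""),
                 width = length(master)),
            class = "msa")
}

#' Stack equal-length sequences into an MSA
#'
#' For indel-free families the alignment is the plain stack of sequences.
#'
#' @param seqs named character vector of equal-length sequences.
#' @return an \code{msa} object.
#' @export
msa_from_stack <- function(seqs) {
  w <- unique(nchar(seqs))
  if (length(w) != 1) stop("sequences differ in length; align them instead")
  structure(list(ids = names(seqs), rows = setNames(unname(seqs), names(seqs)),
                 width = w), class = "msa")
}

#' Write/read an MSA as aligned FASTA (gap "-")
#' @param msa an \code{msa}.
#' @param path file path.
#' @return the path (write) or an \code{msa} (read).
#' @export
write_msa <- function(msa, path) {
  write_fasta(setNames(msa$rows, msa$ids), path)
}

#' @rdname write_msa
#' @export
read_msa <- function(path) {
  seqs <- read_fasta(path)
  structure(list(ids = names(seqs), rows = seqs,
                 width = unique(nchar(seqs))), class = "msa")
}

# transition prior used to spread the +1 pseudocount, per source state
TRANS_PRIOR <- list(M = c(MM = 0.9, MD = 0.05, MI = 0.05),
                    I = c(IM = 0.7, II = 0.3),
                    D = c(DM = 0.7, DD = 0.3))

#' Build a profile model from an MSA
#'
#' Columns whose gap fraction is at most \code{gap_fraction_max} become match
#' states. Match emissions use the +background pseudocount rule
#' \eqn{P(a) = (count_a + bg_a) / (n_rows + 1)}; insert states emit the
#' background; transitions are estimated from the observed per-row state
#' paths with one total pseudocount spread by a standard transition prior.
#' There is no insert state before the first or after the last match column
#' (unannotated sequence flanks are free in glocal scoring).
#'
#' @param msa an \code{msa}.
#' @param gap_fraction_max maximum gap fraction for a match column.
#' @param background residue background frequencies (default uniform 0.05).
#' @return an object of class \code{profile_model}.
#' @export
build_profile <- function(msa, gap_fraction_max = 0.5, background = NULL) {
  if (length(msa$rows) == 0) stop("empty MSA")
  if (is.null(background))
    background <- setNames(rep(0.05, 20), AA_ALPHABET)
  rows <- lapply(msa$rows, function(r) strsplit(r, "")[[1]])
  mat <- do.call(rbind, rows)
  nr <- nrow(mat)
  gap_frac <- colMeans(mat == "-")
  match_cols <- which(gap_frac <= gap_fraction_max)
  L <- length(match_cols)
  if (L == 0) stop("MSA has no match columns at this gap fraction")

  # P(a) = (count_a + bg_a) / (n_observed + 1); n_observed excludes gap rows
  # so every emission vector sums to one
  em <- matrix(0, L, 20, dimnames = list(NULL, AA_ALPHABET))
  for (k in seq_len(L)) {
    col <- mat[, match_cols[k]]
    cnt <- table(factor(col[col != "-"], levels = AA_ALPHABET))
    em[k, ] <- (as.numeric(cnt) + background) / (sum(cnt) + 1)
  }

  # per-row state paths over junctions 0..L; count transitions
  tc <- matrix(0, L + 1, 7,
               dimnames = list(NULL, c("MM", "MD", "MI", "IM", "II", "DM", "DD")))
  is_match <- logical(ncol(mat)); is_match[match_cols] <- TRUE
  for (r in seq_len(nr)) {
    row <- mat[r, ]
    prev <- "M"; junction <- 0L
    for (c in seq_len(ncol(mat))) {
      if (is_match[c]) {
        st <- if (row[c] == "-") "D" else "M"
        key <- paste0(prev, st)
        tc[junction + 1L, key] <- tc[junction + 1L, key] + 1
        prev <- st
        junction <- junction + 1L
      } else if (row[c] != "-") {
        # insert residues before the first / after the last match column are
        # flanks, not inserts
        if (junction == 0L || junction == L) next
        key <- paste0(prev, "I")
        if (prev == "D") next  # D->I not modelled; fold into the flank-free path
        tc[junction + 1L, key] <- tc[junction + 1L, key] + 1
        prev <- "I"
      }
    }
    key <- paste0(prev, "M")  # exit to END
    tc[L + 1L, key] <- tc[L + 1L, key] + 1
  }
  trans <- matrix(0, L + 1, 7, dimnames = dimnames(tc))
  for (j in seq_len(L + 1)) {
    for (src in c("M", "I", "D")) {
      keys <- names(TRANS_PRIOR[[src]])
      prior <- TRANS_PRIOR[[src]]
      # structurally absent transitions at the boundaries
      if (j == 1 && src == "M") prior["MI"] <- 0
      if (j == L + 1) {
        if (src == "M") { prior["MD"] <- 0; prior["MI"] <- 0 }
        if (src == "I") prior["II"] <- 0
        if (src == "D") prior["DD"] <- 0
      }
      if (sum(prior) == 0) next
      prior <- prior / sum(prior)
      cnt <- tc[j, keys]
      p <- (cnt + prior) / (sum(cnt) + 1)
      trans[j, keys] <- p
    }
  }
  structure(list(n_match_states = L,
                 match_emissions = em,
                 insert_emissions = background,
                 transitions = trans,
                 background = background,
                 match_columns = match_cols,
                 trusted_cutoff = NULL,
                 noise_cutoff = NULL,
                 seed_ids = msa$ids),
            class = "profile_model")
}

# log2-odds emission and log2 transition matrices for the Viterbi kernel
model_log_matrices <- function(model) {
  em <- log2(sweep(model$match_emissions, 2, model$background, "/"))
  tl <- log2(model$transitions)
  tl[model$transitions == 0] <- -Inf
  list(em = em, tl = tl)
}

#' Consensus sequence of a profile model
#' @param model a \code{profile_model}.
#' @return the per-state argmax residue string.
#' @export
model_consensus <- function(model) {
  paste(AA_ALPHABET[apply(model$match_emissions, 1, which.max)], collapse = "")
}

#' Score a sequence against a profile model
#'
#' Best-path (Viterbi) log-odds score in bits, glocal mode: the model is
#' traversed end to end while sequence flanks outside the aligned region are
#' null-scored and free.
#'
#' @param model a \code{profile_model}.
#' @param seq protein sequence.
#' @return score in bits.
#' @export
score_sequence <- function(model, seq) {
  if (nchar(seq) == 0) stop("empty sequence")
  lm <- model_log_matrices(model)
  .cpp_viterbi_bits(lm$em, lm$tl, list(encode_seq(seq)))[1]
}

# batch scoring; seqs: named character vector
score_sequences <- function(model, seqs) {
  lm <- model_log_matrices(model)
  enc <- lapply(seqs, encode_seq)
  setNames(.cpp_viterbi_bits(lm$em, lm$tl, enc), names(seqs))
}

# Viterbi-aligned residue per match state ("-" for delete), used by the
# conserved-site filter during model extension
viterbi_match_residues <- function(model, seq) {
  lm <- model_log_matrices(model)
  r <- .cpp_viterbi_path(lm$em, lm$tl, encode_seq(seq))
  res <- r$match_residues
  out <- rep("-", model$n_match_states)
  out[res >= 0] <- AA_ALPHABET[res[res >= 0] + 1L]
  out
}

#' Calibrate trusted and noise cutoffs
#'
#' Pfam convention: the trusted cutoff is the lowest score of a curated
#' member, the noise cutoff the highest score of a curated non-member.
#'
#' @param model a \code{profile_model}.
#' @param positives bit scores of curated members.
#' @param negatives bit scores of curated non-members.
#' @return the model with \code{trusted_cutoff} and \code{noise_cutoff} set.
#' @export
calibrate_cutoffs <- function(model, positives, negatives) {
  if (length(positives) == 0 || length(negatives) == 0)
    stop("both score lists must be non-empty")
  trusted <- min(positives)
  noise <- max(negatives)
  if (trusted <= noise)
    stop(sprintf("non-separable cutoffs: min(positives) = %.2f <= max(negatives) = %.2f",
                 trusted, noise))
  model$trusted_cutoff <- trusted
  model$noise_cutoff <- noise
  model
}

#' Classify a bit score against the model cutoffs
#'
#' \code{member} at or above trusted, \code{candidate} strictly between noise
#' and trusted (the "unknown NusG^SP" zone), \code{none} at or below noise.
#'
#' @param bits bit score(s).
#' @param model calibrated \code{profile_model}.
#' @return character vector of zones.
#' @export
classify_hit <- function(bits, model) {
  if (is.null(model$trusted_cutoff) || is.null(model$noise_cutoff))
    stop("model cutoffs are not set; run calibrate_cutoffs first")
  ifelse(bits >= model$trusted_cutoff, "member",
         ifelse(bits > model$noise_cutoff, "candidate", "none"))
}

#' Scan proteomes with a calibrated profile model
#'
#' Scores every gene of every genome and reports all hits in the member or
#' candidate zone, flagging the best hit per genome.
#'
#' @param model calibrated \code{profile_model}.
#' @param genomes list of \code{genome} objects (or a \code{genome_world}).
#' @return data frame with gene_id, genome_id, bit_score, zone, best_in_genome.
#' @export
scan_proteomes <- function(model, genomes) {
  if (inherits(genomes, "genome_world")) genomes <- genomes$genomes
  if (length(genomes) == 0)
    return(data.frame(gene_id = character(0), genome_id = character(0),
                      bit_score = numeric(0), zone = character(0),
                      best_in_genome = logical(0)))
  out <- lapply(genomes, function(gn) {
    bits <- score_sequences(model, setNames(gn$genes$protein_sequence,
                                            gn$genes$gene_id))
    zone <- classify_hit(bits, model)
    keep <- zone != "none"
    if (!any(keep)) return(NULL)
    df <- data.frame(gene_id = gn$genes$gene_id[keep],
                     genome_id = gn$genome_id,
                     bit_score = unname(bits[keep]), zone = zone[keep],
                     stringsAsFactors = FALSE)
    df$best_in_genome <- df$bit_score == max(df$bit_score)
    df
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(gene_id = character(0), genome_id = character(0),
                      bit_score = numeric(0), zone = character(0),
                      best_in_genome = logical(0))
  rownames(res) <- NULL
  res
}

#' Full family-model building workflow
#'
#' Reproduces the stepwise profile construction: seed MSA, initial profile,
#' scan of the genome pool, collection of hits passing a provisional filter
#' (positive bits plus required residues at configured conserved sites),
#' redundancy reduction of the union at \code{identity_reduction}, re-
#' alignment, final profile, and cutoff calibration from labelled positive
#' and negative scores.
#'
#' @param seed_seqs named character vector of >= 5 seed sequences.
#' @param pool list of \code{genome} objects (or a \code{genome_world}).
#' @param positives_ids,negatives_ids gene ids of curated members and curated
#'   non-members used for cutoff calibration (genes absent from the pool are
#'   ignored). Uncurated genes — the "unknown" fraction — belong to neither.
#' @param identity_reduction identity level for redundancy reduction.
#' @param required_sites named character vector: 1-based match-state position
#'   -> required residue; hits lacking any required residue in their Viterbi
#'   alignment are dropped from the extension (the automated analogue of a
#'   manual conserved-position screen). NULL disables the filter.
#' @param params an \code{\link{align_params}}.
#' @param gap_fraction_max passed to \code{\link{build_profile}}.
#' @return a calibrated \code{profile_model}.
#' @export
build_family_model <- function(seed_seqs, pool, positives_ids, negatives_ids,
                               identity_reduction = 0.80,
                               required_sites = NULL,
                               params = align_params(),
                               gap_fraction_max = 0.5) {
  if (length(seed_seqs) < 5) stop("need at least 5 seed sequences")
  if (inherits(pool, "genome_world")) pool <- pool$genomes
  seed_msa <- if (length(unique(nchar(seed_seqs))) == 1)
    msa_from_stack(seed_seqs) else center_star_msa(seed_seqs, params)
  initial <- build_profile(seed_msa, gap_fraction_max)

  all_seqs <- unlist(lapply(unname(pool), function(gn)
    setNames(gn$genes$protein_sequence, gn$genes$gene_id)))
  bits <- score_sequences(initial, all_seqs)
  cand <- names(bits)[bits > 0]
  if (!is.null(required_sites) && length(cand) > 0) {
    pos <- as.integer(names(required_sites))
    keep <- vapply(cand, function(id) {
      mr <- viterbi_match_residues(initial, all_seqs[[id]])
      all(mr[pos] == unname(required_sites))
    }, logical(1))
    cand <- cand[keep]
  }
  extended <- all_seqs[cand]
  union_set <- c(seed_seqs, extended[setdiff(names(extended), names(seed_seqs))])

  red <- reduce_redundancy(union_set, identity_reduction, params)
  reps <- union_set[red$representatives]
  final_msa <- if (length(unique(nchar(reps))) == 1 && length(reps) >= 2)
    msa_from_stack(reps) else center_star_msa(reps, params)
  final <- build_profile(final_msa, gap_fraction_max)

  fb <- score_sequences(final, all_seqs)
  pos_scores <- fb[intersect(positives_ids, names(fb))]
  neg_scores <- fb[intersect(negatives_ids, names(fb))]
  calibrate_cutoffs(final, pos_scores, neg_scores)
}

#' Write / read a profile model as plain text
#'
#' A documented plain-text format: header lines (\code{#key<TAB>value}) with
#' length, cutoffs and seed ids, then per-state emission and transition
#' tables.
#'
#' @param model a \code{profile_model}.
#' @param path file path.
#' @return the path (write) or a \code{profile_model} (read).
#' @export
write_profile <- function(model, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c(sprintf("#profile\trfahkit"),
               sprintf("#n_match_states\t%d", model$n_match_states),
               sprintf("#trusted_cutoff\t%s",
                       if (is.null(model$trusted_cutoff)) "NA"
                       else format(model$trusted_cutoff, digits = 10)),
               sprintf("#noise_cutoff\t%s",
                       if (is.null(model$noise_cutoff)) "NA"
                       else format(model$noise_cutoff, digits = 10)),
               sprintf("#seed_ids\t%s", paste(model$seed_ids, collapse = ",")),
               sprintf("#background\t%s",
                       paste(format(model$background, digits = 10),
                             collapse = ","))), con)
  writeLines("#match_emissions", con)
  write.table(format(model$match_emissions, digits = 10), con, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = TRUE)
  writeLines("#transitions", con)
  write.table(format(model$transitions, digits = 10), con, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  kv <- function(key) {
    l <- grep(paste0("^#", key, "\t"), lines, value = TRUE)[1]
    strsplit(l, "\t")[[1]][2]
  }
  L <- as.integer(kv("n_match_states"))
  tr <- kv("trusted_cutoff"); no <- kv("noise_cutoff")
  bg <- as.numeric(strsplit(kv("background"), ",")[[1]])
  i_em <- which(lines == "#match_emissions")
  i_tr <- which(lines == "#transitions")
  em <- as.matrix(read.delim(text = lines[(i_em + 1):(i_em + 1 + L)],
                             check.names = FALSE))
  dimnames(em) <- list(NULL, colnames(em))
  trans <- as.matrix(read.delim(text = lines[(i_tr + 1):(i_tr + 2 + L)],
                                check.names = FALSE))
  dimnames(trans) <- list(NULL, colnames(trans))
  structure(list(n_match_states = L, match_emissions = em,
                 insert_emissions = setNames(bg, AA_ALPHABET),
                 transitions = trans,
                 background = setNames(bg, AA_ALPHABET),
                 match_columns = seq_len(L),
                 trusted_cutoff = if (tr == "NA") NULL else as.numeric(tr),
                 noise_cutoff = if (no == "NA") NULL else as.numeric(no),
                 seed_ids = strsplit(kv("seed_ids"), ",")[[1]]),
            class = "profile_model")
}
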