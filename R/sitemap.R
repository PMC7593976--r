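# Mapping of reference-numbered functional residues onto alignment columns
# and classification of each sequence's state at those sites as identical,
# conservative, divergent or gap.

# standard physico-chemical partition of the 20 residues used to call
# conservative substitutions (the workflow's display convention never
# defines one, so a standard grouping is used and is configurable)
CONSERVATIVE_GROUPS <- list(basic = c("K", "R", "H"),
                            acidic = c("D", "E"),
                            amide = c("N", "Q"),
                            hydroxyl = c("S", "T"),
                            aliphatic = c("I", "L", "V", "M"),
                            aromatic = c("F", "W", "Y"),
                            small = c("A", "G"),
                            cysteine = "C",
                            proline = "P")

#' Functional-site scheme
#'
#' Numbered functional residues of a reference sequence (e.g., the
#' RfaH-style DNA-binding, RNAP-binding, autoinhibition and Rho-loop sites
#' in E. coli numbering), with a partition of the residues into
#' conservative groups.
#'
#' @param reference_id id of the reference sequence carrying the numbering.
#' @param sites data frame with columns position (1-based in the ungapped
#'   reference), canonical_residue, site_label.
#' @param conservative_groups list of residue groups partitioning the 20
#'   amino acids.
#' @return an object of class \code{site_scheme}.
#' @export
site_scheme <- function(reference_id, sites,
                        conservative_groups = CONSERVATIVE_GROUPS) {
  stopifnot(all(c("position", "canonical_residue", "site_label") %in%
                  names(sites)))
  if (is.unsorted(sites$position, strictly = TRUE))
    stop("site positions must be strictly increasing")
  all_res <- sort(unname(unlist(conservative_groups)))
  if (!identical(all_res, sort(AA_ALPHABET)))
    stop("conservative groups must partition the 20 residues")
  structure(list(reference_id = reference_id, sites = sites,
                 conservative_groups = conservative_groups),
            class = "site_scheme")
}

#' Default site scheme for a planted paralog family
#'
#' The ten planted RfaH-like functional residues (DNA binding, RNAP binding,
#' autoinhibition and the Rho-loop positions), numbered in ungapped
#' reference coordinates.
#'
#' @param reference_id reference sequence id.
#' @return a \code{site_scheme}.
#' @export
default_site_scheme <- function(reference_id) {
  labs <- c("K10_dna", "E48_autoinhibition", "F56_rnap", "R73_dna",
            "F81_rnap", "I93_autoinhibition", "F130_autoinhibition",
            "L145_rho_loop", "I146_rho_loop", "N147_rho_loop")
  site_scheme(reference_id,
              data.frame(position = as.integer(names(PARALOG_SITES)),
                         canonical_residue = unname(PARALOG_SITES),
                         site_label = labs, stringsAsFactors = FALSE))
}

#' Map site positions to alignment columns
#'
#' Column of the k-th non-gap reference character for reference position k.
#' A warning is recorded when the reference residue at a mapped column
#' differs from the canonical residue.
#'
#' @param msa an \code{msa} containing the reference.
#' @param scheme a \code{site_scheme}.
#' @return named integer vector site_label -> 0-based column index, with a
#'   \code{mismatches} attribute listing discordant sites.
#' @export
map_positions <- function(msa, scheme) {
  ref <- msa$rows[[scheme$reference_id]]
  if (is.null(ref)) stop("reference sequence not in MSA")
  chars <- strsplit(ref, "")[[1]]
  non_gap <- which(chars != "-")
  pos <- scheme$sites$position
  if (any(pos > length(non_gap)))
    stop("site position exceeds ungapped reference length")
  cols <- non_gap[pos] - 1L
  obs <- chars[non_gap[pos]]
  mism <- scheme$sites$site_label[obs != scheme$sites$canonical_residue]
  if (length(mism) > 0)
    warning("reference residue differs from canonical at: ",
            paste(mism, collapse = ", "))
  structure(setNames(cols, scheme$sites$site_label), mismatches = mism)
}

#' Annotate per-sequence site states
#'
#' For every sequence and site: \code{identical} when the observed residue
#' equals the canonical one, \code{conservative} when it falls in the same
#' conservative group, \code{gap} for a gap character, otherwise
#' \code{divergent}.
#'
#' @inheritParams map_positions
#' @return data frame sequence_id, site_label, observed_residue, state.
#' @export
annotate_states <- function(msa, scheme) {
  cols <- suppressWarnings(map_positions(msa, scheme))
  group_of <- setNames(rep(names(scheme$conservative_groups),
                           lengths(scheme$conservative_groups)),
                       unlist(scheme$conservative_groups))
  rows <- list()
  for (sid in msa$ids) {
    chars <- strsplit(msa$rows[[sid]], "")[[1]]
    for (k in seq_len(nrow(scheme$sites))) {
      obs <- chars[cols[k] + 1L]
      canon <- scheme$sites$canonical_residue[k]
      state <- if (obs == "-") "gap"
        else if (obs == canon) "identical"
        else if (group_of[[obs]] == group_of[[canon]]) "conservative"
        else "divergent"
      rows[[length(rows) + 1L]] <- data.frame(
        sequence_id = sid, site_label = scheme$sites$site_label[k],
        observed_residue = obs, state = state, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-clade fraction of canonical-like site states
#'
#' For each clade and site, the fraction of members whose state is identical
#' or conservative; gap observations are excluded from the denominator.
#'
#' @param table an \code{\link{annotate_states}} result.
#' @param clades named list clade label -> character vector of sequence ids.
#' @return data frame clade, site_label, fraction, n.
#' @export
clade_state_frequencies <- function(table, clades) {
  rows <- list()
  for (cl in names(clades)) {
    members <- clades[[cl]]
    if (length(members) == 0) stop("empty clade: ", cl)
    sub <- table[table$sequence_id %in% members, ]
    for (site in unique(table$site_label)) {
      st <- sub$state[sub$site_label == site]
      st <- st[st != "gap"]
      if (length(st) == 0)
        stop(sprintf("clade %s has only gaps at site %s", cl, site))
      rows[[length(rows) + 1L]] <- data.frame(
        clade = cl, site_label = site,
        fraction = mean(st %in% c("identical", "conservative")),
        n = length(st), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
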