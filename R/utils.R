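# shared helpers: residue alphabets, RNG sub-streams, small I/O utilities

# the 20 standard amino acids, in the row order used throughout
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# encode a protein string as 0-based indices into `alphabet`
encode_seq <- function(seq, alphabet = AA_ALPHABET) {
  if (nchar(seq) == 0L) return(integer(0))
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  idx <- match(chars, alphabet)
  if (anyNA(idx)) {
    bad <- unique(chars[is.na(idx)])
    stop("sequence contains non-amino-acid character(s): ",
         paste(bad, collapse = ", "))
  }
  idx - 1L
}

decode_seq <- function(idx, alphabet = AA_ALPHABET) {
  paste(alphabet[idx + 1L], collapse = "")
}

# deterministic 31-bit string hash (exact in double arithmetic)
str_hash <- function(x) {
  h <- 0
  for (c in utf8ToInt(x)) h <- (h * 31 + c) %% 2147483647
  h
}

#' Derive a reproducible sub-stream seed
#'
#' Combines a base seed with string labels into a new seed below 2^31, so that
#' each (family, genome) or pipeline stage gets its own independent,
#' label-stable random stream.
#'
#' @param seed integer base seed.
#' @param ... character labels identifying the sub-stream.
#' @return an integer seed.
#' @export
substream_seed <- function(seed, ...) {
  h <- as.numeric(seed) %% 2147483647
  for (lab in c(...)) h <- (h * 48271 + str_hash(as.character(lab))) %% 2147483647
  as.integer(h)
}

# evaluate `expr` under a temporary seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# TSV writers shared by all modules: "#"-prefixed header, 6 significant digits
write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 6))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  if (nrow(df) > 0)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  header <- sub("^#", "", readLines(path, n = 1L))
  df <- read.delim(path, header = FALSE, skip = 1L, sep = "\t",
                   stringsAsFactors = FALSE)
  if (nrow(df) == 0) df <- as.data.frame(matrix(nrow = 0, ncol = length(strsplit(header, "\t")[[1]])))
  names(df) <- strsplit(header, "\t")[[1]]
  df
}

write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  set <- Biostrings::AAStringSet(unlist(seqs))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  setNames(as.character(set), names(set))
}
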