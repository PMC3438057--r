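#' Read protein sequences from FASTA
#'
#' Thin wrapper over Biostrings; ids are parsed up to the first whitespace
#' of the description line.
#'
#' @param path FASTA file (multi-record, wrapped lines allowed).
#' @return Named character vector of upper-case residue strings.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("cannot read FASTA: no such file: ", path)
  ss <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- vapply(strsplit(names(ss), "\\s+"), `[`, "", 1L)
  seqs
}

#' Write protein sequences to FASTA
#'
#' @param seqs Named character vector of residue strings.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Read an aligned-FASTA multiple sequence alignment
#'
#' @param path Aligned FASTA with `-` gap characters; all rows must have
#'   equal length.
#' @return Named character vector of aligned rows (an `msa`).
#' @export
read_msa <- function(path) {
  seqs <- read_fasta(path)
  if (length(seqs) == 0L) stop("empty MSA file: ", path)
  if (length(unique(nchar(seqs))) != 1L) {
    stop("MSA rows have unequal lengths in ", path)
  }
  seqs
}

# msa (character vector of aligned rows) -> character matrix, one row per
# sequence, one column per alignment column
.msa_matrix <- function(msa) {
  if (length(msa) == 0L) stop("empty MSA")
  if (length(unique(nchar(msa))) != 1L) stop("MSA rows have unequal lengths")
  do.call(rbind, strsplit(toupper(msa), ""))
}
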