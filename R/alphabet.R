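#' The 20-letter amino-acid alphabet
#'
#' Residue order used for every frequency vector and score matrix in the
#' package (the classic NCBI ordering ARNDCQEGHILKMFPSTWYV).
#'
#' @return Character vector of the 20 canonical residues, in order.
#' @export
aa_alphabet <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

# letter -> index lookup covering the canonical alphabet only; ambiguity
# codes (X, B, Z, U, J, O, *) map to NA and are handled by the caller's
# policy: background-average scores in alignment, zero counts in profile
# construction.
.aa_index <- local({
  idx <- setNames(seq_len(20L), aa_alphabet())
  function(letters) unname(idx[letters])
})

#' Split residue strings into index vectors
#'
#' @param seq Character scalar of residue letters.
#' @return Integer vector of 1-based alphabet indices; `NA` for any
#'   non-canonical letter (ambiguity codes such as X/B/Z/U/*).
#' @export
aa_indices <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  .aa_index(strsplit(toupper(seq), "")[[1]])
}

# Per-residue score column for a sequence against an arbitrary l x 20 score
# matrix; ambiguous residues get the background-weighted average column.
.residue_cell_scores <- function(score_rows, seq_idx, background) {
  ncolumns <- length(seq_idx)
  out <- matrix(0, nrow = nrow(score_rows), ncol = ncolumns)
  avg <- as.numeric(score_rows %*% background)
  for (j in seq_len(ncolumns)) {
    k <- seq_idx[j]
    out[, j] <- if (is.na(k)) avg else score_rows[, k]
  }
  out
}
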