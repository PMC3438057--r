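#' Affine-gap Smith-Waterman over a position score matrix
#'
#' Optimal local alignment where `cell[i, j]` gives the score for pairing
#' row position i with column position j; a gap of length k costs
#' `gap_open + k * gap_extend`. Traceback is deterministic (ties prefer
#' diagonal, then a gap consuming a row, then a gap consuming a column).
#'
#' @param cell Numeric matrix of pairing scores.
#' @param gap_open,gap_extend Non-negative gap penalties.
#' @return List with `score` (0 when no positive-scoring alignment exists)
#'   and `pairs`, an L x 2 matrix of 0-based (row, column) aligned pairs,
#'   strictly increasing in both coordinates.
#' @export
sw_align <- function(cell, gap_open = 11, gap_extend = 1) {
  stopifnot(is.matrix(cell), nrow(cell) >= 1, ncol(cell) >= 1,
            gap_open >= 0, gap_extend >= 0)
  .sw_align_cells(cell, as.numeric(gap_open), as.numeric(gap_extend))
}

# score of a given pair list under cell scores + affine gap costs (used by
# re-scoring invariant checks and identity computations)
.score_pairs <- function(cell, pairs, gap_open, gap_extend) {
  if (nrow(pairs) == 0) return(0)
  s <- sum(cell[cbind(pairs[, 1] + 1L, pairs[, 2] + 1L)])
  if (nrow(pairs) > 1) {
    dq <- diff(pairs[, 1])
    dp <- diff(pairs[, 2])
    gaps <- c(dq - 1L, dp - 1L)
    gaps <- gaps[gaps > 0]
    if (length(gaps)) s <- s - sum(gap_open + gaps * gap_extend)
  }
  s
}
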