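#' Convert a domain profile to position-specific scores
#'
#' Each profile column's observed frequencies are blended with
#' data-dependent pseudocounts (data weight alpha = n_obs - 1, prior weight
#' `beta`) into target frequencies Q, which become integer log-odds scores
#' `round(scale * ln(Q_i / p_i) / lambda_u)` after the scaling step that
#' pins the score system's ungapped lambda to the underlying matrix's (see
#' [scale_pssm()]). Gap-only profile columns are dropped; `col_map` links
#' score rows back to original profile columns.
#'
#' @param profile A `domain_profile`.
#' @param matrix An `aa_matrix`.
#' @param beta Pseudocount weight (default 10).
#' @param scale Integer score scale (default 1 = matrix units).
#' @return List with `scores` (kept-columns x 20 integer), `float_scores`,
#'   `col_map` (0-based original column of each score row), `n_obs` (per
#'   kept column), `lambda`, `multiplier`, and the matrix's gapped
#'   statistics.
#' @export
profile_scores <- function(profile, matrix = read_matrix(), beta = 10,
                           scale = 1) {
  keep <- which(rowSums(profile$freqs) > 0)
  if (length(keep) == 0L) stop("degenerate profile: all columns are gap-only")
  Q <- matrix(0, nrow = length(keep), ncol = 20,
              dimnames = list(NULL, aa_alphabet()))
  for (r in seq_along(keep)) {
    j <- keep[r]
    Q[r, ] <- target_frequencies(profile$freqs[j, ],
                                 alpha = max(0, profile$n_obs[j] - 1),
                                 matrix = matrix, beta = beta)
  }
  sc <- .scores_from_targets(Q, matrix, scale)
  list(scores = sc$scores, float_scores = sc$float_scores,
       col_map = keep - 1L, n_obs = profile$n_obs[keep],
       lambda = matrix$ungapped_lambda, multiplier = sc$multiplier,
       gapped_lambda = matrix$gapped_lambda, gapped_K = matrix$gapped_K,
       gapped_H = matrix$gapped_H, scale = scale)
}

#' Align a query sequence to a profile's score matrix
#'
#' Optimal affine-gap local alignment of query residues against profile
#' columns. Ambiguous query residues score as the background-weighted
#' average of the column's scores.
#'
#' @param query Residue string.
#' @param pscores Result of [profile_scores()].
#' @param gap_open,gap_extend Gap costs (defaults 11 / 1).
#' @param background Background frequencies for ambiguity scoring.
#' @return A `profile_hit` (raw_score, aligned 0-based
#'   (query_pos, profile_col) pairs, half-open query/profile ranges) or
#'   `NULL` when no alignment scores above 0.
#' @export
align_query_to_profile <- function(query, pscores, gap_open = 11,
                                   gap_extend = 1,
                                   background = read_matrix()$background) {
  qidx <- aa_indices(query)
  if (length(qidx) == 0L) stop("empty query")
  # cell[i, j]: query position i vs kept profile column j
  cell <- t(.residue_cell_scores(pscores$scores, qidx, background))
  al <- sw_align(cell, gap_open, gap_extend)
  if (al$score <= 0) return(NULL)
  pairs <- al$pairs
  pairs[, 2] <- pscores$col_map[pairs[, 2] + 1L]
  structure(list(profile_id = NA_character_,
                 raw_score = al$score,
                 bit_score = NA_real_, evalue = NA_real_,
                 aligned_pairs = pairs,
                 query_range = c(pairs[1, 1], pairs[nrow(pairs), 1] + 1L),
                 profile_range = c(pairs[1, 2], pairs[nrow(pairs), 2] + 1L)),
            class = "profile_hit")
}

#' Search a profile library with a query sequence
#'
#' The reverse-PSSM search stage: profiles whose maximum effective
#' observation count falls below `min_max_obs` are excluded before
#' alignment (insufficiently diverse domain models), each remaining profile
#' is aligned by exhaustive gapped local alignment, and hits with E-value
#' above `inclusion_evalue` are dropped. The search-space size for E-values
#' treats the filtered library as one corpus (total kept profile columns).
#'
#' @param query Residue string (non-empty).
#' @param library A `profile_library`.
#' @param matrix An `aa_matrix`.
#' @param inclusion_evalue Inclusion threshold (default 0.05).
#' @param min_max_obs Minimum max-column observation count (default 6).
#' @param beta Pseudocount weight for profile scores.
#' @param gap_open,gap_extend Gap costs.
#' @param max_hsps Maximum local alignments per profile (default 1; larger
#'   values return non-overlapping suboptimal alignments by iterative
#'   masking of each hit's query-range x profile-range block).
#' @return List of `profile_hit` sorted by E-value (ties by profile id);
#'   empty list when nothing passes (the caller's cue to fall back to a
#'   plain matrix search).
#' @export
search_domains <- function(query, library, matrix = read_matrix(),
                           inclusion_evalue = 0.05, min_max_obs = 6,
                           beta = 10, gap_open = 11, gap_extend = 1,
                           max_hsps = 1) {
  if (!nzchar(query)) stop("empty query")
  if (length(library$profiles) == 0L) stop("empty profile library")
  keep <- Filter(function(p) max(p$n_obs) >= min_max_obs, library$profiles)
  if (length(keep) == 0L) return(list())
  pscores <- lapply(keep, profile_scores, matrix = matrix, beta = beta)
  total_cols <- sum(vapply(pscores, function(s) nrow(s$scores), 0L))
  qidx <- aa_indices(query)
  eff <- effective_lengths(length(qidx), total_cols, length(keep),
                           matrix$gapped_lambda, matrix$gapped_K,
                           matrix$gapped_H)
  hits <- list()
  for (id in names(keep)) {
    ps <- pscores[[id]]
    cell0 <- t(.residue_cell_scores(ps$scores, qidx, matrix$background))
    cell <- cell0
    for (h in seq_len(max_hsps)) {
      al <- sw_align(cell, gap_open, gap_extend)
      if (al$score <= 0) break
      pairs <- al$pairs
      qr <- c(pairs[1, 1], pairs[nrow(pairs), 1] + 1L)
      pr0 <- c(pairs[1, 2], pairs[nrow(pairs), 2] + 1L)
      ev <- evalue(al$score, matrix$gapped_lambda, matrix$gapped_K,
                   eff$m_eff, eff$n_eff)
      orig <- pairs
      orig[, 2] <- ps$col_map[orig[, 2] + 1L]
      hit <- structure(
        list(profile_id = id, raw_score = al$score,
             bit_score = bit_score(al$score, matrix$gapped_lambda,
                                   matrix$gapped_K),
             evalue = ev, aligned_pairs = orig,
             query_range = qr,
             profile_range = c(orig[1, 2], orig[nrow(orig), 2] + 1L)),
        class = "profile_hit")
      if (ev <= inclusion_evalue) hits[[length(hits) + 1L]] <- hit
      if (h == max_hsps) break
      cell[(qr[1] + 1L):qr[2], (pr0[1] + 1L):pr0[2]] <- -Inf
    }
  }
  if (length(hits) == 0L) return(list())
  ord <- order(vapply(hits, `[[`, 0, "evalue"),
               vapply(hits, `[[`, "", "profile_id"),
               -vapply(hits, `[[`, 0, "raw_score"))
  hits[ord]
}

#' @export
print.profile_hit <- function(x, ...) {
  cat(sprintf("Profile hit %s  score %d  E = %.3g  query [%d,%d)  cols [%d,%d)\n",
              x$profile_id, as.integer(x$raw_score), x$evalue,
              x$query_range[1], x$query_range[2],
              x$profile_range[1], x$profile_range[2]))
  invisible(x)
}

# encode aligned pairs as diagonal blocks "qstart,pstart,len;..." (0-based)
.pairs_to_blocks <- function(pairs) {
  if (nrow(pairs) == 0) return("")
  brk <- c(TRUE, diff(pairs[, 1]) != 1L | diff(pairs[, 2]) != 1L)
  starts <- which(brk)
  ends <- c(starts[-1] - 1L, nrow(pairs))
  paste(sprintf("%d,%d,%d", pairs[starts, 1], pairs[starts, 2],
                ends - starts + 1L), collapse = ";")
}

.blocks_to_pairs <- function(txt) {
  if (!nzchar(txt)) return(matrix(0L, 0, 2))
  do.call(rbind, lapply(strsplit(txt, ";")[[1]], function(b) {
    v <- as.integer(strsplit(b, ",")[[1]])
    cbind(v[1] + seq_len(v[3]) - 1L, v[2] + seq_len(v[3]) - 1L)
  }))
}

#' Write domain-search hits as TSV
#'
#' Columns: query id, profile id, raw score, bit score, E-value, 1-based
#' inclusive query and profile ranges, and the aligned pairs as 0-based
#' diagonal blocks `qstart,pstart,len;...`.
#'
#' @param hits List of `profile_hit`.
#' @param query_id Query identifier.
#' @param path Output path.
#' @export
write_domain_hits <- function(hits, query_id, path) {
  df <- data.frame(
    qseqid = rep(query_id, length(hits)),
    profile = vapply(hits, `[[`, "", "profile_id"),
    score = vapply(hits, function(h) as.integer(h$raw_score), 0L),
    bitscore = round(vapply(hits, `[[`, 0, "bit_score"), 2),
    evalue = signif(vapply(hits, `[[`, 0, "evalue"), 4),
    qstart = vapply(hits, function(h) h$query_range[1] + 1L, 0L),
    qend = vapply(hits, function(h) h$query_range[2], 0L),
    pstart = vapply(hits, function(h) h$profile_range[1] + 1L, 0L),
    pend = vapply(hits, function(h) h$profile_range[2], 0L),
    blocks = vapply(hits, function(h) .pairs_to_blocks(h$aligned_pairs), ""))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
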