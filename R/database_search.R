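# shared engine: position score rows (l x 20 integer) vs every subject in
# a database, with gapped Karlin-Altschul statistics
.search_engine <- function(score_rows, query, query_id, seqs, stats,
                           background, report_evalue, gap_open, gap_extend) {
  if (length(seqs) == 0L) stop("empty database")
  db_res <- sum(nchar(seqs))
  eff <- effective_lengths(nrow(score_rows), db_res, length(seqs),
                           stats$lambda, stats$K, stats$H)
  qres <- strsplit(toupper(query), "")[[1]]
  hits <- list()
  for (sid in names(seqs)) {
    sidx <- aa_indices(seqs[[sid]])
    cell <- .residue_cell_scores(score_rows, sidx, background)
    al <- sw_align(cell, gap_open, gap_extend)
    if (al$score <= 0) next
    ev <- evalue(al$score, stats$lambda, stats$K, eff$m_eff, eff$n_eff)
    if (ev > report_evalue) next
    pairs <- al$pairs
    sres <- strsplit(toupper(seqs[[sid]]), "")[[1]]
    ident <- mean(qres[pairs[, 1] + 1L] == sres[pairs[, 2] + 1L])
    hits[[length(hits) + 1L]] <- structure(
      list(query_id = query_id, subject_id = sid,
           raw_score = al$score,
           bit_score = bit_score(al$score, stats$lambda, stats$K),
           evalue = ev, identity_fraction = ident,
           aligned_pairs = pairs,
           query_range = c(pairs[1, 1], pairs[nrow(pairs), 1] + 1L),
           subject_range = c(pairs[1, 2], pairs[nrow(pairs), 2] + 1L),
           self_hit = identical(sid, query_id)),
      class = "search_hit")
  }
  if (length(hits) == 0L) return(list())
  ord <- order(vapply(hits, `[[`, 0, "evalue"),
               -vapply(hits, `[[`, 0, "bit_score"),
               vapply(hits, `[[`, "", "subject_id"))
  hits[ord]
}

.as_db <- function(db) {
  if (is.character(db) && length(db) == 1L && is.null(names(db))) {
    read_fasta(db) # treated as a path; read_fasta errors if missing
  } else {
    stopifnot(is.character(db), !is.null(names(db)))
    as.list(toupper(db))
  }
}

#' Search a protein database with a PSSM
#'
#' Optimal affine-gap local alignment of the PSSM's score rows against
#' every subject sequence, with E-values from the gapped statistics on
#' BLAST-convention effective lengths. Hits with E-value at or below the
#' report threshold are returned sorted by E-value (ties: bit score
#' descending, then subject id); a hit whose subject id equals the query
#' id is flagged as a self hit.
#'
#' @param pssm A `delta_pssm`.
#' @param db FASTA path or named character vector of subject sequences.
#' @param report_evalue Report threshold (default 10, the BLAST
#'   convention).
#' @param gap_open,gap_extend Gap costs (defaults 11 / 1).
#' @param background Background frequencies (ambiguity scoring).
#' @return List of `search_hit`.
#' @export
search_database <- function(pssm, db, report_evalue = 10, gap_open = 11,
                            gap_extend = 1,
                            background = read_matrix()$background) {
  seqs <- .as_db(db)
  stats <- list(lambda = pssm$gapped_lambda, K = pssm$gapped_K,
                H = pssm$gapped_H)
  .search_engine(pssm$scores, pssm$query, pssm$query_id, seqs, stats,
                 background, report_evalue, gap_open, gap_extend)
}

#' Plain substitution-matrix (BLASTP-style) database search
#'
#' The fallback route for queries without domain matches: identical search
#' contract to [search_database()], with each query position scored by the
#' matrix row of its residue (ambiguity codes score zero). Hit-for-hit
#' equivalent to searching with the query-only PSSM.
#'
#' @param query Residue string.
#' @param db FASTA path or named character vector.
#' @param matrix An `aa_matrix`.
#' @param query_id Query identifier.
#' @param report_evalue,gap_open,gap_extend As in [search_database()].
#' @return List of `search_hit`.
#' @export
blastp_fallback <- function(query, db, matrix = read_matrix(),
                            query_id = "query", report_evalue = 10,
                            gap_open = 11, gap_extend = 1) {
  qidx <- aa_indices(query)
  if (length(qidx) == 0L) stop("empty query")
  rows <- matrix(0L, nrow = length(qidx), ncol = 20,
                 dimnames = list(NULL, aa_alphabet()))
  for (i in seq_along(qidx)) {
    if (!is.na(qidx[i])) rows[i, ] <- matrix$scores[qidx[i], ]
  }
  stats <- list(lambda = matrix$gapped_lambda, K = matrix$gapped_K,
                H = matrix$gapped_H)
  .search_engine(rows, query, query_id, .as_db(db), stats,
                 matrix$background, report_evalue, gap_open, gap_extend)
}

#' @export
print.search_hit <- function(x, ...) {
  cat(sprintf("%s vs %s  score %d  bits %.1f  E = %.3g  id %.0f%%%s\n",
              x$query_id, x$subject_id, as.integer(x$raw_score),
              x$bit_score, x$evalue, 100 * x$identity_fraction,
              if (x$self_hit) "  [self]" else ""))
  invisible(x)
}

#' Write search hits in BLAST tabular (outfmt 6 style) TSV
#'
#' The 12 standard columns (qseqid, sseqid, pident, length, mismatch,
#' gapopen, qstart, qend, sstart, send, evalue, bitscore) with 1-based
#' inclusive coordinates. `mismatch` counts non-identical aligned pairs and
#' `gapopen` the number of gap runs.
#'
#' @param hits List of `search_hit`.
#' @param path Output path.
#' @export
write_hits_tsv <- function(hits, path) {
  rows <- lapply(hits, function(h) {
    p <- h$aligned_pairs
    ngaps <- 0L
    if (nrow(p) > 1) {
      ngaps <- sum(diff(p[, 1]) > 1L) + sum(diff(p[, 2]) > 1L)
    }
    data.frame(qseqid = h$query_id, sseqid = h$subject_id,
               pident = round(100 * h$identity_fraction, 2),
               length = nrow(p),
               mismatch = sum(round(nrow(p) * (1 - h$identity_fraction))),
               gapopen = ngaps,
               qstart = h$query_range[1] + 1L, qend = h$query_range[2],
               sstart = h$subject_range[1] + 1L, send = h$subject_range[2],
               evalue = signif(h$evalue, 4), bitscore = round(h$bit_score, 1))
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(qseqid = character(0), sseqid = character(0),
               pident = numeric(0), length = integer(0),
               mismatch = integer(0), gapopen = integer(0),
               qstart = integer(0), qend = integer(0), sstart = integer(0),
               send = integer(0), evalue = numeric(0), bitscore = numeric(0))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a BLAST tabular hits file
#'
#' @param path TSV written by [write_hits_tsv()] (or any 12-column BLAST
#'   outfmt-6 file).
#' @return data.frame with the 12 standard columns.
#' @export
read_hits_tsv <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  df <- read.delim(path, header = FALSE, col.names = cols,
                   stringsAsFactors = FALSE)
  df
}

#' Write search hits as JSON lines with aligned pairs
#'
#' One JSON object per hit, carrying everything in the TSV dialect plus
#' the 0-based aligned pair list.
#'
#' @param hits List of `search_hit`.
#' @param path Output path.
#' @export
write_hits_jsonl <- function(hits, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (h in hits) {
    obj <- list(query_id = h$query_id, subject_id = h$subject_id,
                raw_score = h$raw_score, bit_score = h$bit_score,
                evalue = h$evalue, identity_fraction = h$identity_fraction,
                query_range = h$query_range, subject_range = h$subject_range,
                aligned_pairs = unname(apply(h$aligned_pairs, 1, c,
                                             simplify = FALSE)),
                self_hit = h$self_hit)
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
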