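#' Collapse profile hits onto the query template
#'
#' Builds the query-template multiple alignment implied by a set of profile
#' hits: exactly one column per query position, each holding the profile
#' columns aligned there. Profile columns aligned to gaps inserted into the
#' query (insertions relative to the query) are discarded by construction
#' since only aligned residue pairs are mapped. When the same profile
#' aligns more than once to a query position, only the alignment with the
#' lowest E-value is retained for that position (ties: larger raw score,
#' then smaller profile column). The query residue is added, with one
#' observation, only at positions where it has zero weighted frequency
#' across all contributing profile columns.
#'
#' @param query Residue string.
#' @param hits List of `profile_hit` from [search_domains()].
#' @param library The `profile_library` the hits refer to.
#' @return List (one per query position) of `collapsed_column`: fields
#'   `query_pos` (0-based), `contributions` (list of `profile_id`,
#'   `profile_col`, `freqs`, `weight`), `query_included`, `query_residue`.
#' @export
collapse <- function(query, hits, library) {
  qlen <- nchar(query)
  qres <- strsplit(toupper(query), "")[[1]]
  qidx <- aa_indices(query)
  # per position: named list keyed by profile id -> best candidate
  best <- vector("list", qlen)
  for (h in hits) {
    prof <- library$profiles[[h$profile_id]]
    if (is.null(prof)) stop("hit references unknown profile: ", h$profile_id)
    p <- h$aligned_pairs
    for (k in seq_len(nrow(p))) {
      q <- p[k, 1] + 1L
      col <- p[k, 2] + 1L
      if (sum(prof$freqs[col, ]) == 0) next # gap-only profile column
      cand <- list(profile_id = h$profile_id, profile_col = col - 1L,
                   evalue = h$evalue, raw_score = h$raw_score)
      cur <- best[[q]][[h$profile_id]]
      replace <- is.null(cur) ||
        cand$evalue < cur$evalue ||
        (cand$evalue == cur$evalue && cand$raw_score > cur$raw_score) ||
        (cand$evalue == cur$evalue && cand$raw_score == cur$raw_score &&
           cand$profile_col < cur$profile_col)
      if (replace) {
        if (is.null(best[[q]])) best[[q]] <- list()
        best[[q]][[h$profile_id]] <- cand
      }
    }
  }
  lapply(seq_len(qlen), function(q) {
    sel <- best[[q]]
    if (length(sel)) sel <- sel[order(names(sel))]
    contribs <- lapply(sel, function(cand) {
      prof <- library$profiles[[cand$profile_id]]
      list(profile_id = cand$profile_id,
           profile_col = cand$profile_col,
           freqs = prof$freqs[cand$profile_col + 1L, ],
           weight = prof$n_obs[cand$profile_col + 1L])
    })
    # an ambiguity code is never represented by a profile column, so it
    # counts as unobserved (and contributes nothing downstream)
    qfreq <- if (is.na(qidx[q])) 0 else {
      sum(vapply(contribs, function(ct) ct$freqs[qidx[q]], 0))
    }
    structure(list(query_pos = q - 1L,
                   contributions = unname(contribs),
                   query_included = qfreq == 0,
                   query_residue = qres[q]),
              class = "collapsed_column")
  })
}

#' Observed frequencies and data weight of a collapsed column
#'
#' Profile contributions are mixed proportionately to their effective
#' observation counts; the query residue enters as a single observation
#' only when the column marks it included. The data weight alpha is the
#' total observation count minus one (the pseudocount mix treats one
#' observation as carrying no frequency information), floored at zero.
#'
#' @param column A `collapsed_column`.
#' @param background Background frequencies, used only for the degenerate
#'   case of an ambiguous query residue with no contributions.
#' @return List with `f` (20-vector summing to 1) and `alpha` (>= 0).
#' @export
observed_frequencies <- function(column,
                                 background = read_matrix()$background) {
  f <- setNames(numeric(20), aa_alphabet())
  total_w <- 0
  for (ct in column$contributions) {
    f <- f + ct$weight * ct$freqs
    total_w <- total_w + ct$weight
  }
  if (column$query_included) {
    k <- .aa_index(column$query_residue)
    if (!is.na(k)) {
      f[k] <- f[k] + 1
      total_w <- total_w + 1
    } else if (total_w == 0) {
      # ambiguous query residue, nothing else observed: neutral column
      return(list(f = background / sum(background), alpha = 0))
    }
  }
  list(f = f / sum(f), alpha = max(0, total_w - 1))
}

#' Data-dependent pseudocount target frequencies
#'
#' Blends observed column frequencies f with the pseudocount prior
#' \eqn{g_i = \sum_j (f_j / p_j) q_{ij}} (normalised), the residue
#' relationships encoded in the substitution matrix's target frequencies,
#' as \eqn{Q = (\alpha f + \beta g) / (\alpha + \beta)}.
#'
#' @param f Observed frequencies (20-vector summing to 1).
#' @param alpha Data weight (effective observations minus one), >= 0.
#' @param matrix An `aa_matrix` supplying q and p.
#' @param beta Pseudocount weight, > 0.
#' @return Target frequency vector Q summing to 1.
#' @export
target_frequencies <- function(f, alpha, matrix = read_matrix(), beta = 10) {
  stopifnot(alpha >= 0, beta > 0, length(f) == 20)
  g <- as.numeric(matrix$target_freqs %*% (f / matrix$background))
  g <- g / sum(g)
  Q <- (alpha * f + beta * g) / (alpha + beta)
  Q <- Q / sum(Q)
  names(Q) <- aa_alphabet()
  Q
}

# round half away from zero (round() rounds half to even)
.round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Q rows -> float log-odds scores and scaled integer scores.
# Q = 0 maps to the documented floor: min matrix score - 1 (in matrix
# units), scaled like every other score.
.scores_from_targets <- function(Q, matrix, scale = 1) {
  lam <- matrix$ungapped_lambda
  p <- matrix$background
  floor_score <- min(matrix$scores) - 1
  fs <- t(apply(Q, 1, function(q) {
    s <- ifelse(q > 0, log(q / p) / lam, floor_score)
    pmax(s, floor_score)
  }))
  mult <- .pssm_multiplier(fs, matrix)
  list(float_scores = fs,
       scores = matrix(as.integer(.round_half_away(mult * scale * fs)),
                       nrow = nrow(fs), dimnames = list(NULL, aa_alphabet())),
       multiplier = mult)
}

#' Convert target-frequency rows to integer PSSM scores
#'
#' Scores take the log-odds form `round(scale * ln(Q_ij / p_j) / lambda_u)`;
#' a zero target frequency maps to the floor score (the matrix minimum
#' minus one).
#'
#' @param Q_rows l x 20 matrix of target frequencies.
#' @param background Length-20 background probabilities.
#' @param lambda_u Ungapped lambda of the underlying matrix.
#' @param scale Integer up-scaling factor (default 1 = matrix units).
#' @param floor_score Score (in pre-scale units) assigned where Q = 0;
#'   default -5, the shipped matrix's minimum score minus one.
#' @return l x 20 integer matrix.
#' @export
pssm_scores <- function(Q_rows, background, lambda_u, scale = 1,
                        floor_score = -5) {
  fs <- t(apply(Q_rows, 1, function(q) {
    s <- ifelse(q > 0, log(q / background) / lambda_u, floor_score)
    pmax(s, floor_score)
  }))
  matrix(as.integer(.round_half_away(scale * fs)), nrow = nrow(fs),
         dimnames = list(NULL, aa_alphabet()))
}

# multiplier c pinning the PSSM's ungapped lambda to the matrix's: the
# lambda of c * S solves at lambda(S) / c, so c = lambda(S) / lambda_u
# exactly (well below the 1e-4 relative requirement).
.pssm_multiplier <- function(float_scores, matrix) {
  l <- nrow(float_scores)
  w <- rep(matrix$background, each = l) / l
  lam <- .solve_lambda_weighted(as.numeric(float_scores), as.numeric(w))
  lam / matrix$ungapped_lambda
}

#' Rescale a PSSM so its ungapped lambda matches the underlying matrix
#'
#' The scaling step used before assigning gapped statistics: computes the
#' PSSM's own ungapped lambda against the background (positions weighted
#' uniformly), rescales all scores by `c = lambda_pssm / lambda_matrix`
#' so the rescaled system's lambda equals the matrix's exactly, re-rounds
#' to integers, and stamps the matrix's gapped (lambda, K) onto the result
#' for E-value computation.
#'
#' @param pssm A `delta_pssm` (uses its float scores).
#' @param matrix An `aa_matrix`.
#' @return The input `delta_pssm` with updated `scores`, `multiplier`,
#'   `gapped_lambda`, `gapped_K`, `gapped_H`.
#' @export
scale_pssm <- function(pssm, matrix = read_matrix()) {
  mult <- .pssm_multiplier(pssm$float_scores, matrix)
  pssm$multiplier <- mult
  pssm$scores <- matrix(
    as.integer(.round_half_away(mult * pssm$scale * pssm$float_scores)),
    nrow = nrow(pssm$float_scores), dimnames = list(NULL, aa_alphabet()))
  pssm$lambda <- matrix$ungapped_lambda
  pssm$gapped_lambda <- matrix$gapped_lambda
  pssm$gapped_K <- matrix$gapped_K
  pssm$gapped_H <- matrix$gapped_H
  pssm
}

#' Build a domain-enhanced PSSM for a query
#'
#' The full construction: search the profile library, collapse the hits
#' onto the query template, form observation-weighted column frequencies,
#' apply data-dependent pseudocounts, convert to integer log-odds scores
#' and pin the statistics by rescaling. A query with no qualifying domain
#' hits yields the query-only PSSM, whose rows reproduce the underlying
#' substitution matrix's rows for each query residue (the BLASTP fallback
#' identity).
#'
#' @param query Residue string (or single named element of [read_fasta()]).
#' @param library A `profile_library`.
#' @param matrix An `aa_matrix`.
#' @param query_id Identifier recorded in the PSSM.
#' @param inclusion_evalue,min_max_obs,beta,gap_open,gap_extend,max_hsps
#'   Domain-search and pseudocount parameters (defaults 0.05, 6, 10, 11, 1,
#'   1).
#' @param scale Integer score scale (default 1).
#' @param hits Optional precomputed hit list (skips the library search).
#' @return A `delta_pssm`: `query_id`, `query`, `length`, `scores` (l x 20
#'   integer), `float_scores`, `target_freqs`, `alpha` (per-column data
#'   weights), `lambda`, `multiplier`, gapped statistics, `n_hits`,
#'   `fallback` (TRUE when no domain hit contributed), and per-column
#'   `provenance` (contributing profile ids).
#' @export
build_pssm <- function(query, library = NULL, matrix = read_matrix(),
                       query_id = "query", inclusion_evalue = 0.05,
                       min_max_obs = 6, beta = 10, gap_open = 11,
                       gap_extend = 1, max_hsps = 1, scale = 1,
                       hits = NULL) {
  if (is.null(hits)) {
    hits <- if (is.null(library) || length(library$profiles) == 0L) list()
    else search_domains(query, library, matrix,
                        inclusion_evalue = inclusion_evalue,
                        min_max_obs = min_max_obs, beta = beta,
                        gap_open = gap_open, gap_extend = gap_extend,
                        max_hsps = max_hsps)
  }
  cols <- collapse(query, hits,
                   if (is.null(library)) profile_library(list()) else library)
  l <- length(cols)
  Q <- matrix(0, nrow = l, ncol = 20, dimnames = list(NULL, aa_alphabet()))
  alpha <- numeric(l)
  prov <- vector("list", l)
  for (i in seq_len(l)) {
    ofreq <- observed_frequencies(cols[[i]], matrix$background)
    alpha[i] <- ofreq$alpha
    Q[i, ] <- target_frequencies(ofreq$f, ofreq$alpha, matrix, beta)
    prov[[i]] <- vapply(cols[[i]]$contributions, `[[`, "", "profile_id")
  }
  sc <- .scores_from_targets(Q, matrix, scale)
  structure(list(query_id = query_id, query = toupper(query), length = l,
                 scores = sc$scores, float_scores = sc$float_scores,
                 target_freqs = Q, alpha = alpha,
                 lambda = matrix$ungapped_lambda,
                 multiplier = sc$multiplier, scale = scale,
                 gapped_lambda = matrix$gapped_lambda,
                 gapped_K = matrix$gapped_K, gapped_H = matrix$gapped_H,
                 n_hits = length(hits), fallback = length(hits) == 0L,
                 provenance = prov),
            class = "delta_pssm")
}

#' @export
print.delta_pssm <- function(x, ...) {
  cat("Domain-enhanced PSSM for", x$query_id, "-", x$length, "positions\n")
  covered <- sum(x$alpha > 0)
  cat(sprintf("  %d domain hit(s); %d/%d positions with domain evidence%s\n",
              x$n_hits, covered, x$length,
              if (x$fallback) " (query-only: plain matrix search)" else ""))
  cat(sprintf("  lambda %.4f  gapped (lambda, K) = (%.3f, %.3f)  multiplier %.4f\n",
              x$lambda, x$gapped_lambda, x$gapped_K, x$multiplier))
  invisible(x)
}

#' @export
summary.delta_pssm <- function(object, ...) {
  print(object)
  cat("  alpha: min", format(min(object$alpha), digits = 3),
      " median", format(stats::median(object$alpha), digits = 3),
      " max", format(max(object$alpha), digits = 3), "\n")
  profs <- unique(unlist(object$provenance))
  if (length(profs)) cat("  contributing profiles:",
                         paste(profs, collapse = ", "), "\n")
  invisible(object)
}

#' Write a PSSM to file
#'
#' Two dialects: `"native"` is the package's structured text with target
#' frequencies, per-column data weights and provenance (losslessly read
#' back by [read_pssm()]); `"ascii"` is a BLAST-style readable table of
#' integer scores (position, residue, 20 scores), for interoperability.
#'
#' @param pssm A `delta_pssm`.
#' @param path Output path.
#' @param dialect `"native"` or `"ascii"`.
#' @export
write_pssm <- function(pssm, path, dialect = c("native", "ascii")) {
  dialect <- match.arg(dialect)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) cat(..., "\n", file = con, sep = "")
  if (dialect == "ascii") {
    w("# BLAST-style PSSM: query ", pssm$query_id,
      "  lambda ", format(pssm$gapped_lambda), "  K ", format(pssm$gapped_K))
    w(paste(c("pos", "aa", aa_alphabet()), collapse = "\t"))
    qres <- strsplit(pssm$query, "")[[1]]
    for (i in seq_len(pssm$length)) {
      w(paste(c(i, qres[i], pssm$scores[i, ]), collapse = "\t"))
    }
    return(invisible(path))
  }
  w("# deltapssm PSSM")
  w("format_version 1")
  w("query_id ", pssm$query_id)
  w("query ", pssm$query)
  w("length ", pssm$length)
  for (f in c("lambda", "multiplier", "scale", "gapped_lambda", "gapped_K",
              "gapped_H", "n_hits")) {
    w(f, " ", format(pssm[[f]], digits = 15))
  }
  w("fallback ", if (pssm$fallback) 1 else 0)
  w("alpha ", paste(format(pssm$alpha, digits = 9), collapse = " "))
  w("scores")
  for (i in seq_len(pssm$length)) w(paste(pssm$scores[i, ], collapse = " "))
  w("target_freqs")
  for (i in seq_len(pssm$length)) {
    w(paste(format(pssm$target_freqs[i, ], digits = 9), collapse = " "))
  }
  w("provenance")
  for (i in seq_len(pssm$length)) {
    ids <- pssm$provenance[[i]]
    w(if (length(ids)) paste(ids, collapse = ",") else "-")
  }
  w("end")
  invisible(path)
}

#' Read a native-dialect PSSM file
#'
#' @param path File written by [write_pssm()] with `dialect = "native"`.
#' @return A `delta_pssm` (float scores reconstructed from target
#'   frequencies).
#' @export
read_pssm <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  kv <- list()
  i <- 1L
  while (i <= length(lines)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (tok[1] %in% c("scores", "target_freqs", "provenance")) break
    val <- tok[-1]
    num <- suppressWarnings(as.numeric(val))
    kv[[tok[1]]] <- if (anyNA(num)) paste(val, collapse = " ") else num
    i <- i + 1L
  }
  l <- as.integer(kv$length)
  grab <- function(i, what) {
    if (trimws(lines[i]) != what) stop("parse error in ", path, " line ", i,
                                       ": expected '", what, "'")
    m <- do.call(rbind, lapply(lines[(i + 1L):(i + l)], function(x) {
      as.numeric(strsplit(trimws(x), "\\s+")[[1]])
    }))
    dimnames(m) <- list(NULL, aa_alphabet())
    list(m = m, nxt = i + l + 1L)
  }
  b1 <- grab(i, "scores")
  b2 <- grab(b1$nxt, "target_freqs")
  i <- b2$nxt
  stopifnot(trimws(lines[i]) == "provenance")
  prov <- lapply(lines[(i + 1L):(i + l)], function(x) {
    x <- trimws(x)
    if (x == "-") character(0) else strsplit(x, ",")[[1]]
  })
  mat_stub <- list(background = read_matrix()$background)
  structure(list(query_id = kv$query_id, query = kv$query, length = l,
                 scores = matrix(as.integer(b1$m), nrow = l,
                                 dimnames = list(NULL, aa_alphabet())),
                 float_scores = t(apply(b2$m, 1, function(q) {
                   log(pmax(q, 1e-300) / mat_stub$background) / kv$lambda
                 })),
                 target_freqs = b2$m, alpha = kv$alpha,
                 lambda = kv$lambda, multiplier = kv$multiplier,
                 scale = kv$scale, gapped_lambda = kv$gapped_lambda,
                 gapped_K = kv$gapped_K, gapped_H = kv$gapped_H,
                 n_hits = as.integer(kv$n_hits),
                 fallback = kv$fallback == 1, provenance = prov),
            class = "delta_pssm")
}
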