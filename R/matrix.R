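#' Read a substitution-matrix file
#'
#' Parses the package's structured-text matrix format: scalar header fields
#' (`name`, `alphabet`, ungapped and gapped Karlin-Altschul parameters, gap
#' costs) followed by named blocks `background` (one line, 20 values),
#' `scores` (20 lines of 20 integers) and `target_freqs` (20 lines of 20
#' reals). The default file ships BLOSUM62 with Robinson-Robinson background
#' frequencies; its target frequencies are the ones implied by the integer
#' scores at the matrix's ungapped lambda, so that q_ij = p_i p_j
#' exp(lambda * s_ij) holds exactly.
#'
#' @param path Path to a matrix file; defaults to the shipped BLOSUM62.
#' @return An object of class `aa_matrix`: list with `name`, `alphabet`,
#'   `scores` (20x20 integer), `target_freqs` (20x20, summing to 1),
#'   `background` (length-20, summing to 1), `ungapped_lambda`, `ungapped_K`,
#'   `ungapped_H`, `gap_open`, `gap_extend`, `gapped_lambda`, `gapped_K`,
#'   `gapped_H`.
#' @export
read_matrix <- function(path = system.file("extdata", "blosum62.mat",
                                           package = "deltapssm")) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "\\s+")
  out <- list()
  i <- 1L
  read_block <- function(i, nlines) {
    m <- do.call(rbind, lapply(toks[i:(i + nlines - 1L)], as.numeric))
    list(m = m, nxt = i + nlines)
  }
  while (i <= length(toks)) {
    key <- toks[[i]][1]
    if (key == "scores" || key == "target_freqs") {
      b <- read_block(i + 1L, 20L)
      out[[key]] <- b$m
      i <- b$nxt
    } else if (key == "background") {
      out$background <- as.numeric(toks[[i + 1L]])
      i <- i + 2L
    } else {
      val <- toks[[i]][2]
      num <- suppressWarnings(as.numeric(val))
      out[[key]] <- if (is.na(num)) val else num
      i <- i + 1L
    }
  }
  need <- c("alphabet", "scores", "target_freqs", "background",
            "ungapped_lambda", "gapped_lambda", "gapped_K", "gapped_H",
            "gap_open", "gap_extend")
  missing <- setdiff(need, names(out))
  if (length(missing) > 0) {
    stop("malformed matrix file ", path, ": missing field(s) ",
         paste(missing, collapse = ", "))
  }
  ab <- strsplit(out$alphabet, "")[[1]]
  stopifnot(identical(ab, aa_alphabet()))
  dimnames(out$scores) <- dimnames(out$target_freqs) <- list(ab, ab)
  names(out$background) <- ab
  out$alphabet <- ab
  structure(out, class = "aa_matrix")
}

#' Write a substitution matrix in the package's text format
#'
#' Lossless round-trip with [read_matrix()] for the numerical precision
#' written (scores are integers; frequencies use 15 significant digits).
#'
#' @param matrix An `aa_matrix` object.
#' @param path Output path.
#' @export
write_matrix <- function(matrix, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) cat(..., "\n", file = con, sep = "")
  w("# deltapssm substitution-matrix file")
  w("format_version 1")
  w("name ", matrix$name)
  w("alphabet ", paste(matrix$alphabet, collapse = ""))
  for (f in c("ungapped_lambda", "ungapped_K", "ungapped_H",
              "gap_open", "gap_extend",
              "gapped_lambda", "gapped_K", "gapped_H")) {
    w(f, " ", format(matrix[[f]], digits = 15))
  }
  w("background")
  w(paste(format(matrix$background, digits = 15), collapse = " "))
  w("scores")
  for (i in 1:20) w(paste(matrix$scores[i, ], collapse = " "))
  w("target_freqs")
  for (i in 1:20) w(paste(format(matrix$target_freqs[i, ], digits = 15),
                          collapse = " "))
  invisible(path)
}

#' @export
print.aa_matrix <- function(x, ...) {
  cat("Substitution matrix", x$name, "\n")
  cat("  ungapped lambda:", format(x$ungapped_lambda, digits = 6),
      " H:", format(x$ungapped_H, digits = 4), "\n")
  cat("  gap costs ", x$gap_open, "/", x$gap_extend,
      "  gapped lambda: ", x$gapped_lambda, "  K: ", x$gapped_K, "\n",
      sep = "")
  invisible(x)
}

#' Solve for the ungapped Karlin-Altschul lambda of a score system
#'
#' Finds the unique positive root of
#' \deqn{\sum_{ij} p_i p_j e^{\lambda s_{ij}} = 1}
#' by bracketed bisection followed by Newton polishing. A valid score system
#' must have strictly negative expected score and at least one positive
#' score; otherwise no positive root exists.
#'
#' @param scores 20x20 numeric score matrix.
#' @param background Length-20 background probabilities (sums to 1).
#' @param tol Relative tolerance on lambda (default 1e-9).
#' @return Positive numeric lambda.
#' @export
solve_ungapped_lambda <- function(scores, background, tol = 1e-9) {
  pp <- outer(background, background)
  .solve_lambda_weighted(as.numeric(scores), as.numeric(pp), tol)
}

# Shared root-finder: weights w_k sum to 1 over score entries s_k; solves
# sum w_k exp(lambda s_k) = 1. Used for both square matrices and PSSMs
# (where positions are weighted uniformly).
.solve_lambda_weighted <- function(s, w, tol = 1e-9) {
  es <- sum(w * s)
  if (!any(s > 0)) stop("invalid scoring system: no positive score")
  if (es >= 0) stop("invalid scoring system: non-negative expected score")
  f <- function(l) sum(w * exp(l * s)) - 1
  lo <- 0
  hi <- 0.5
  while (f(hi) < 0) {
    lo <- hi
    hi <- hi * 2
    if (hi > 1e4) stop("lambda bracket failed")
  }
  for (k in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
    if ((hi - lo) < tol * mid) break
  }
  l <- (lo + hi) / 2
  # Newton polish
  for (k in 1:5) {
    fl <- f(l)
    dl <- sum(w * s * exp(l * s))
    step <- fl / dl
    l2 <- l - step
    if (l2 > 0 && is.finite(l2)) l <- l2
    if (abs(step) < tol * l) break
  }
  l
}

#' Karlin-Altschul E-value
#'
#' Expected number of chance local alignments scoring at least `raw_score`:
#' \eqn{E = K m n e^{-\lambda S}}.
#'
#' @param raw_score Alignment raw score.
#' @param lambda,K Karlin-Altschul parameters of the scoring system.
#' @param m Effective query (or PSSM) length.
#' @param n Effective database length in residues.
#' @return Non-negative E-value.
#' @export
evalue <- function(raw_score, lambda, K, m, n) {
  stopifnot(lambda > 0, K > 0, m >= 1, n >= 1)
  K * m * n * exp(-lambda * raw_score)
}

#' Bit score from a raw score
#'
#' @inheritParams evalue
#' @return Bit score \eqn{(\lambda S - \ln K) / \ln 2}.
#' @export
bit_score <- function(raw_score, lambda, K) {
  (lambda * raw_score - log(K)) / log(2)
}

#' BLAST-convention effective search-space lengths
#'
#' Computes the standard length adjustment \eqn{\ell} as the fixed point of
#' \deqn{\ell = \frac{\ln(K (m - \ell)(n - N\ell))}{H}}
#' (iterated from 0, capped so the adjusted lengths stay positive), then
#' returns `m_eff = max(1, m - l)` and `n_eff = max(N, n - N * l)` where `N`
#' is the number of database sequences.
#'
#' @param query_len Query length m (residues).
#' @param db_residues Total database residues n.
#' @param db_seqs Number of database sequences N.
#' @param lambda,K Karlin-Altschul parameters used for the statistics.
#' @param H Relative entropy of the scoring system (nats/position).
#' @return List with `m_eff`, `n_eff`, `length_adjustment`.
#' @export
effective_lengths <- function(query_len, db_residues, db_seqs, lambda, K, H) {
  stopifnot(query_len >= 1, db_residues >= 1, db_seqs >= 1, H > 0, K > 0)
  ell <- 0
  for (it in 1:50) {
    m_eff <- query_len - ell
    n_eff <- db_residues - db_seqs * ell
    if (m_eff < 1 || n_eff < 1) break
    ss <- m_eff * n_eff
    new_ell <- log(K * ss) / H
    if (new_ell < 0) new_ell <- 0
    # never adjust away more than the query allows
    new_ell <- min(new_ell, query_len - 1, db_residues / db_seqs - 1)
    if (new_ell < 0) new_ell <- 0
    if (abs(new_ell - ell) < 1e-6) { ell <- new_ell; break }
    ell <- new_ell
  }
  ell <- floor(ell)
  list(m_eff = max(1, query_len - ell),
       n_eff = max(db_seqs, db_residues - db_seqs * ell),
       length_adjustment = ell)
}
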