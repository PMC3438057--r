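# Independent oracles used across the suite. Each deliberately uses a
# different algorithm from the implementation it checks.

# plain interval-doubling bisection for the ungapped lambda root,
# independent of the package's bisection+Newton solver
oracle_lambda_bisect <- function(scores, background, tol = 1e-12) {
  pp <- outer(background, background)
  f <- function(l) sum(pp * exp(l * scores)) - 1
  lo <- 0
  hi <- 0.25
  while (f(hi) < 0) {
    lo <- hi
    hi <- hi * 2
    stopifnot(hi < 1e6)
  }
  for (k in 1:300) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

# random integer substitution matrix that is a valid scoring system
# (symmetric, some positive score, negative expectation under a random
# background)
random_valid_matrix <- function() {
  repeat {
    s <- matrix(sample(-6:3, 400, replace = TRUE, prob = c(rep(2, 7), 2, 1, 1)),
                20, 20)
    s <- pmax(s, t(s)) # symmetrise
    diag(s) <- abs(diag(s)) + sample(1:5, 20, replace = TRUE)
    p <- rexp(20) + 0.05
    p <- p / sum(p)
    es <- sum(outer(p, p) * s)
    if (es < -0.1 && any(s > 0)) return(list(scores = s, background = p))
  }
}

# Affine-gap local alignment score by explicit enumeration over consecutive
# aligned pairs: M[i, j] = cell[i, j] + max(0, max over all earlier pairs
# (i', j') of M[i', j'] minus the two independent gap costs implied by the
# skipped residues). A different algorithm (O(n^2 m^2)) from the Gotoh
# three-state recurrence in the package.
oracle_sw_score <- function(cell, gap_open, gap_extend) {
  n <- nrow(cell)
  m <- ncol(cell)
  gc <- function(k) ifelse(k == 0, 0, gap_open + k * gap_extend)
  M <- matrix(-Inf, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      prev <- 0
      if (i > 1 && j > 1) {
        gci <- gc(i - (1:(i - 1)) - 1)
        gcj <- gc(j - (1:(j - 1)) - 1)
        prev <- max(0, max(M[1:(i - 1), 1:(j - 1), drop = FALSE] -
                             outer(gci, gcj, `+`)))
      }
      M[i, j] <- cell[i, j] + prev
    }
  }
  max(0, max(M))
}

# ROC_n by direct enumeration: walk the ranked list, record the TP count
# above each FP as encountered
oracle_roc_n <- function(labels, n, total_positives) {
  t_i <- numeric(0)
  tp <- 0
  for (lab in labels) {
    if (lab == "TP") tp <- tp + 1
    else t_i <- c(t_i, tp)
  }
  if (length(t_i) < n) t_i <- c(t_i, rep(tp, n - length(t_i)))
  min(1, sum(t_i[seq_len(n)]) / (n * total_positives))
}

# random residue string
random_seq <- function(n) paste(sample(aa_alphabet(), n, TRUE), collapse = "")

# small ungapped toy MSA helper: rows as strings
toy_msa <- function(...) c(...)
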