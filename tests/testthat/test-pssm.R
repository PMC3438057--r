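# a tiny handmade library for collapse tests: profiles with known freqs
fixed_profile <- function(id, freq_rows, n_obs) {
  l <- nrow(freq_rows)
  colnames(freq_rows) <- aa_alphabet()
  structure(list(id = id, length = l, freqs = freq_rows, n_obs = n_obs,
                 consensus = paste(rep("A", l), collapse = ""),
                 description = ""),
            class = "domain_profile")
}

fixed_hit <- function(profile_id, pairs, evalue, raw_score = 100) {
  structure(list(profile_id = profile_id, raw_score = raw_score,
                 bit_score = 50, evalue = evalue,
                 aligned_pairs = pairs,
                 query_range = c(pairs[1, 1], pairs[nrow(pairs), 1] + 1L),
                 profile_range = c(pairs[1, 2], pairs[nrow(pairs), 2] + 1L)),
            class = "profile_hit")
}

point_rows <- function(residues, w = 1) {
  m <- matrix(0, length(residues), 20, dimnames = list(NULL, aa_alphabet()))
  for (i in seq_along(residues)) m[i, residues[i]] <- 1
  m
}

test_that("collapsing no hits yields the query-only alignment", {
  cols <- collapse("ACDEF", list(), profile_library(list()))
  expect_length(cols, 5)
  for (cc in cols) {
    expect_length(cc$contributions, 0)
    expect_true(cc$query_included)
  }
})

test_that("query residue is suppressed exactly when a profile represents it", {
  # profile column 0 gives query residue A weight 0.3 -> suppressed;
  # column 1 gives D zero weight -> included
  fr <- matrix(0, 2, 20, dimnames = list(NULL, aa_alphabet()))
  fr[1, "A"] <- 0.3; fr[1, "V"] <- 0.7
  fr[2, "E"] <- 1
  lib <- profile_library(list(fixed_profile("p1", fr, c(5, 5))))
  hits <- list(fixed_hit("p1", cbind(0:1, 0:1), evalue = 1e-6))
  cols <- collapse("AD", hits, lib)
  expect_false(cols[[1]]$query_included)
  expect_true(cols[[2]]$query_included)
})

test_that("per-column conflicts of one profile resolve to the lowest E-value", {
  fr <- point_rows(c("E", "K"))
  lib <- profile_library(list(fixed_profile("p1", fr, c(9, 3))))
  # two HSPs of the same profile covering query position 0
  h_good <- fixed_hit("p1", cbind(0L, 0L), evalue = 1e-8)
  h_bad <- fixed_hit("p1", cbind(0L, 1L), evalue = 1e-3)
  for (ord in list(list(h_good, h_bad), list(h_bad, h_good))) {
    cols <- collapse("A", ord, profile_library(list(
      fixed_profile("p1", fr, c(9, 3)))))
    expect_length(cols[[1]]$contributions, 1)
    expect_equal(cols[[1]]$contributions[[1]]$profile_col, 0L)
    expect_equal(cols[[1]]$contributions[[1]]$weight, 9)
  }
})

test_that("unknown profiles in hits are an error", {
  h <- fixed_hit("ghost", cbind(0L, 0L), 1e-4)
  expect_error(collapse("A", list(h), profile_library(list())),
               "unknown profile")
})

test_that("observed frequencies mix contributions by observation weight", {
  m <- read_matrix()
  # no contributions, query A: point mass, alpha 0
  c0 <- structure(list(query_pos = 0L, contributions = list(),
                       query_included = TRUE, query_residue = "A"),
                  class = "collapsed_column")
  o0 <- observed_frequencies(c0, m$background)
  expect_equal(o0$f[["A"]], 1)
  expect_equal(o0$alpha, 0)
  # single contribution weight 9, query excluded: f = g, alpha = 8
  g <- setNames(rep(0.05, 20), aa_alphabet())
  c1 <- structure(list(query_pos = 0L,
                       contributions = list(list(profile_id = "p",
                                                 profile_col = 0L,
                                                 freqs = g, weight = 9)),
                       query_included = FALSE, query_residue = "A"),
                  class = "collapsed_column")
  o1 <- observed_frequencies(c1, m$background)
  expect_equal(o1$f, g)
  expect_equal(o1$alpha, 8)
  # two contributions (6, 3) plus included query: alpha = 9
  gA <- setNames(numeric(20), aa_alphabet()); gA["E"] <- 1
  c2 <- structure(list(query_pos = 0L,
                       contributions = list(
                         list(profile_id = "p", profile_col = 0L,
                              freqs = g, weight = 6),
                         list(profile_id = "q", profile_col = 0L,
                              freqs = gA, weight = 3)),
                       query_included = TRUE, query_residue = "A"),
                  class = "collapsed_column")
  o2 <- observed_frequencies(c2, m$background)
  hand <- 6 * g + 3 * gA
  hand["A"] <- hand["A"] + 1
  expect_equal(o2$f, hand / sum(hand), tolerance = 1e-12)
  expect_equal(o2$alpha, 9)
})

test_that("pseudocount blending obeys its limits and normalisation", {
  m <- read_matrix()
  set.seed(41)
  for (rep in 1:25) {
    f <- rexp(20)
    f <- f / sum(f)
    g <- target_frequencies(f, alpha = 0, matrix = m)
    # pure prior at alpha = 0
    gg <- as.numeric(m$target_freqs %*% (f / m$background))
    expect_equal(unname(g), gg / sum(gg), tolerance = 1e-12)
    # data dominates at huge alpha
    Qbig <- target_frequencies(f, alpha = 1e9, matrix = m)
    expect_lt(max(abs(Qbig - f)), 1e-6)
    expect_equal(sum(g), 1, tolerance = 1e-9)
    expect_equal(sum(Qbig), 1, tolerance = 1e-9)
  }
  # background maps to itself through the prior
  gbg <- target_frequencies(m$background, 0, m)
  expect_equal(unname(gbg), unname(m$background), tolerance = 1e-9)
})

test_that("log-odds scores behave as logs", {
  m <- read_matrix()
  Q1 <- matrix(m$background, 1, 20, dimnames = list(NULL, aa_alphabet()))
  expect_true(all(pssm_scores(Q1, m$background, m$ungapped_lambda) == 0L))
  # rows built from the matrix conditionals q_i./p_i have exact integer
  # log-odds equal to the matrix's score rows
  cond <- m$target_freqs / m$background
  sc <- pssm_scores(cond, m$background, m$ungapped_lambda)
  expect_equal(unname(sc), unname(m$scores), ignore_attr = TRUE)
  # doubling every ratio shifts each float score by ln2/lambda: realised as
  # an exact +1-bit shift at scale = lambda/ln2
  scale_bits <- m$ungapped_lambda / log(2)
  s1 <- pssm_scores(cond, m$background, m$ungapped_lambda,
                    scale = 1000 * scale_bits)
  s2 <- pssm_scores(2 * cond, m$background, m$ungapped_lambda,
                    scale = 1000 * scale_bits)
  expect_true(all(abs((s2 - s1) - 1000L) <= 1L))
})

test_that("scaling is a fixed point on matrix-equal PSSMs", {
  m <- read_matrix()
  set.seed(42)
  q <- random_seq(25)
  pssm <- build_pssm(q, query_id = "fx")
  expect_equal(pssm$multiplier, 1, tolerance = 1e-10)
  # rescaled system's lambda matches the matrix's within 1e-4 relative,
  # checked with the independent bisection oracle on the scaled-up PSSM
  pssm32 <- build_pssm(q, query_id = "fx32", scale = 32)
  w <- rep(m$background, each = pssm32$length) / pssm32$length
  f <- function(l) sum(w * exp(l * as.numeric(pssm32$scores))) - 1
  lo <- 1e-6; hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  for (i in 1:200) { mid <- (lo + hi) / 2; if (f(mid) < 0) lo <- mid else hi <- mid }
  lam32 <- (lo + hi) / 2
  expect_equal(lam32 * 32, m$ungapped_lambda,
               tolerance = 2e-4)
  # doubling input float scores halves the recovered lambda
  half <- deltapssm:::.solve_lambda_weighted(2 * as.numeric(pssm$float_scores), w)
  full <- deltapssm:::.solve_lambda_weighted(as.numeric(pssm$float_scores), w)
  expect_equal(half, full / 2, tolerance = 1e-8)
  # an all-positive PSSM is rejected
  bad <- pssm
  bad$float_scores <- abs(bad$float_scores) + 1
  expect_error(scale_pssm(bad, m), "expected score")
})

test_that("query-only PSSMs reproduce the substitution matrix", {
  m <- read_matrix()
  set.seed(43)
  for (rep in 1:5) {
    q <- random_seq(sample(10:40, 1))
    pssm <- build_pssm(q, query_id = "qo")
    expect_true(pssm$fallback)
    qi <- aa_indices(q)
    for (i in seq_along(qi)) {
      expect_equal(unname(pssm$scores[i, ]), unname(m$scores[qi[i], ]))
    }
    expect_equal(rowSums(pssm$target_freqs), rep(1, pssm$length),
                 tolerance = 1e-9)
  }
})

test_that("the collapse and PSSM are invariant to hit order", {
  m <- read_matrix()
  sim <- simulate_benchmark(sim_config(seed = 17))
  set.seed(44)
  lib <- simulate_profile_library(sim)
  q <- simulate_family_members(sim, "f1.s2.a", 1)$seqs[[1]]
  hits <- search_domains(q, lib, m, inclusion_evalue = 1)
  expect_gt(length(hits), 1)
  p1 <- build_pssm(q, lib, m, hits = hits)
  p2 <- build_pssm(q, lib, m, hits = rev(hits))
  expect_identical(p1$scores, p2$scores)
  expect_equal(p1$target_freqs, p2$target_freqs, tolerance = 1e-14)
})

test_that("removing a profile leaves uncovered columns unchanged", {
  m <- read_matrix()
  sim <- simulate_benchmark(sim_config(seed = 18))
  set.seed(45)
  lib <- simulate_profile_library(sim)
  q <- simulate_family_members(sim, "f2.s1.b", 1)$seqs[[1]]
  hits <- search_domains(q, lib, m, inclusion_evalue = 1)
  expect_gt(length(hits), 1)
  drop_id <- hits[[length(hits)]]$profile_id
  covered <- sort(unique(hits[[length(hits)]]$aligned_pairs[, 1])) + 1L
  kept_hits <- Filter(function(h) h$profile_id != drop_id, hits)
  pa <- build_pssm(q, lib, m, hits = hits)
  pb <- build_pssm(q, lib, m, hits = kept_hits)
  untouched <- setdiff(seq_len(pa$length), covered)
  # column-local quantities are unchanged off the dropped profile's span
  # (integer scores share one global scaling constant, so the comparison
  # is on the pre-scaling quantities)
  expect_identical(pa$target_freqs[untouched, ], pb$target_freqs[untouched, ])
  expect_identical(pa$float_scores[untouched, ], pb$float_scores[untouched, ])
  expect_identical(pa$alpha[untouched], pb$alpha[untouched])
})

test_that("PSSM build is deterministic and round-trips through its file", {
  m <- read_matrix()
  sim <- simulate_benchmark(sim_config(seed = 19))
  set.seed(46)
  lib <- simulate_profile_library(sim)
  q <- simulate_family_members(sim, "f1.s1.b", 1)$seqs[[1]]
  pa <- build_pssm(q, lib, m, query_id = "det")
  pb <- build_pssm(q, lib, m, query_id = "det")
  t1 <- withr::local_tempfile(); t2 <- withr::local_tempfile()
  write_pssm(pa, t1); write_pssm(pb, t2)
  expect_identical(readLines(t1), readLines(t2))
  back <- read_pssm(t1)
  expect_identical(back$scores, pa$scores)
  expect_equal(back$alpha, pa$alpha, tolerance = 1e-8)
  expect_identical(back$provenance, pa$provenance)
  # ascii dialect writes one row per position
  t3 <- withr::local_tempfile()
  write_pssm(pa, t3, dialect = "ascii")
  expect_length(readLines(t3), pa$length + 2L)
})
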