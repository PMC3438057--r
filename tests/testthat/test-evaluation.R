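toy_labels <- function() {
  benchmark_labels(data.frame(
    id = c("a1", "a2", "b1", "c1", "d1"),
    family = c("famA", "famA", "famB", "famC", "famD"),
    superfamily = c("sfA", "sfA", "sfB", "sfC", "sfD"),
    fold = c("foldX", "foldX", "foldX", "foldY", "foldZ")))
}

test_that("pair labeling follows the superfamily/fold rules", {
  lb <- toy_labels()
  expect_equal(label_pair(lb, "a1", "a2"), "TP")     # same superfamily
  expect_equal(label_pair(lb, "a1", "b1"), "ignored") # same fold, diff sf
  expect_equal(label_pair(lb, "a1", "c1"), "FP")     # different fold
  expect_equal(label_pair(lb, "a1", "a1"), "self")
  expect_error(label_pair(lb, "a1", "zz"), "unknown id")
})

test_that("label hierarchies must be functions", {
  bad <- data.frame(id = c("x", "y"), family = c("f1", "f1"),
                    superfamily = c("s1", "s2"), fold = c("F1", "F1"))
  expect_error(benchmark_labels(bad), "inconsistent hierarchy")
})

test_that("pooling removes self and ignored entries and sorts by E-value", {
  lb <- toy_labels()
  res <- data.frame(qseqid = c("a1", "a1", "a1", "a1"),
                    sseqid = c("a1", "a2", "b1", "c1"),
                    evalue = c(1e-20, 1e-5, 1e-4, 1e-3),
                    bitscore = c(200, 50, 40, 30))
  pooled <- pool_results(res, lb)
  expect_equal(nrow(pooled), 2)
  expect_equal(pooled$label, c("TP", "FP"))
})

test_that("ROC_n spans its extremes and matches the enumeration oracle", {
  perfect <- data.frame(label = c(rep("TP", 4), rep("FP", 5)))
  expect_equal(roc_n(perfect, 3, 4)$score, 1.0)
  worst <- data.frame(label = c(rep("FP", 3), rep("TP", 4)))
  expect_equal(roc_n(worst, 3, 4)$score, 0.0)
  hand <- data.frame(label = c("TP", "FP", "TP", "TP", "FP", "FP",
                               "TP", "FP", "FP", "TP"))
  expect_equal(roc_n(hand, 3, 4)$score,
               oracle_roc_n(hand$label, 3, 4))
  expect_error(roc_n(data.frame(label = character(0)), 3, 4), "empty")
})

test_that("ROC_n equals the oracle on random instances and is invariant
           to how many trailing FPs follow the n-th", {
  set.seed(61)
  for (rep in 1:50) {
    len <- sample(5:200, 1)
    lab <- sample(c("TP", "FP"), len, replace = TRUE)
    n <- sample(1:10, 1)
    Tt <- sum(lab == "TP") + sample(0:5, 1)
    if (Tt == 0) next
    df <- data.frame(label = lab)
    expect_equal(roc_n(df, n, Tt)$score, oracle_roc_n(lab, n, Tt))
  }
})

test_that("seeded bootstrap standard errors are reproducible", {
  set.seed(62)
  df <- data.frame(qseqid = sample(sprintf("q%d", 1:6), 60, TRUE),
                   label = sample(c("TP", "FP"), 60, TRUE))
  r1 <- roc_n(df, 5, 30, bootstrap = 200, seed = 7)
  r2 <- roc_n(df, 5, 30, bootstrap = 200, seed = 7)
  expect_identical(r1$se, r2$se)
  expect_gt(r1$se, 0)
})

test_that("per-query ROC5 applies the five-fake-FP padding rule", {
  pq <- list(
    all_tp = rep("TP", 5),   # padded FPs land last: perfect
    empty = character(0),    # padding defines the value: 0
    mixed = c("TP", "FP", "TP"))
  Tq <- c(all_tp = 5, empty = 3, mixed = 2)
  out <- per_query_roc5(pq, Tq)
  expect_equal(unname(out$scores["all_tp"]), 1.0)
  expect_equal(unname(out$scores["empty"]), 0.0)
  expect_equal(unname(out$scores["mixed"]),
               oracle_roc_n(c(pq$mixed, rep("FP", 5)), 5, 2))
  expect_equal(out$exceedance$fraction[out$exceedance$threshold == 0.9],
               1 / 3)
})

test_that("queries with no attainable homolog are excluded with a warning", {
  pq <- list(q1 = c("TP"), q2 = c("FP"))
  Tq <- c(q1 = 1, q2 = 0)
  expect_warning(out <- per_query_roc5(pq, Tq), "excluded")
  expect_identical(names(out$scores), "q1")
})

test_that("alignment quality equals the set arithmetic", {
  A <- cbind(0:9, 0:9)
  expect_equal(alignment_quality(A, A), list(sensitivity = 1, precision = 1))
  B <- cbind(0:7, 20:27)
  expect_equal(alignment_quality(B, A), list(sensitivity = 0, precision = 0))
  # |S|=10, |N|=8, |N ^ S|=6
  N <- rbind(A[1:6, ], cbind(50:51, 60:61))
  expect_equal(alignment_quality(N, A),
               list(sensitivity = 0.6, precision = 0.75))
  # swapping N and S swaps the two measures
  sw <- alignment_quality(A, N)
  expect_equal(sw$sensitivity, 0.75)
  expect_equal(sw$precision, 0.6)
  expect_error(alignment_quality(A, A[0, , drop = FALSE]), "empty reference")
})

test_that("calibration curve equals direct counting and is monotone", {
  res <- data.frame(
    qseqid = c("q1", "q1", "q2", "q2", "q3"),
    evalue = c(1e-6, 0.02, 0.5, 2, 0.05),
    label = c("TP", "FP", "FP", "FP", "TP"))
  grid <- c(1e-8, 0.01, 0.1, 1, 10)
  curve <- evalue_calibration(res, n_queries = 3, grid = grid)
  expect_equal(curve$mean_fp, c(0, 0, 1 / 3, 2 / 3, 1))
  expect_true(!is.unsorted(curve$mean_fp))
  # x below every FP -> 0; x above all -> total FP / queries
  expect_equal(curve$mean_fp[1], 0)
  expect_equal(curve$mean_fp[length(grid)], 3 / 3)
})

test_that("threshold solving recovers the x where the mean crosses a level", {
  res <- data.frame(
    qseqid = rep(sprintf("q%d", 1:10), each = 2),
    evalue = rep(c(0.001 * 1:10), each = 2) + c(0, 5),
    label = "FP")
  # 10 queries; FP E-values 0.001..0.010 then 5.001..5.010
  x <- calibration_threshold(res, target = 0.3, n_queries = 10)
  expect_equal(x, 0.003)
  # at the crossing point the mean equals the (attainable) target exactly
  expect_equal(sum(res$evalue <= x) / 10, 0.3)
  expect_equal(calibration_threshold(res, 5, n_queries = 10), Inf)
  expect_equal(calibration_threshold(res, 0.05, n_queries = 10), 0.001)
})

test_that("overlap regions partition the union of TP sets", {
  mk <- function(subjects, ev) data.frame(
    qseqid = "q", sseqid = subjects, evalue = ev, label = "TP")
  rpm <- list(
    m1 = mk(c("a", "b", "c"), c(1e-8, 1e-6, 1e-4)),
    m2 = mk(c("b", "c", "d"), c(1e-7, 1e-5, 1e-3)),
    m3 = mk(c("c", "e", "f"), c(1e-9, 1e-2, 1e-1)))
  out <- overlap_and_annotation_summary(rpm, thresholds = c(m1 = 1, m2 = 1,
                                                            m3 = 1))
  expect_equal(sum(out$regions$count), 6) # |union| = {a..f}
  # region membership by exhaustive enumeration
  expect_equal(out$regions$count[out$regions$region == "m1&m2&m3"], 1) # c
  expect_equal(out$regions$count[out$regions$region == "m1&m2"], 1)   # b
  # identical result sets give a single all-methods region
  out2 <- overlap_and_annotation_summary(list(m1 = rpm$m1, m2 = rpm$m1),
                                         thresholds = c(m1 = 1, m2 = 1))
  expect_equal(out2$regions$count[out2$regions$region == "m1&m2"], 3)
  expect_equal(sum(out2$regions$count), 3)
})

test_that("annotation fractions follow the shared-domain rules", {
  rpm <- list(m1 = data.frame(qseqid = c("q", "q"), sseqid = c("s1", "s2"),
                              evalue = c(1e-6, 1e-6), label = "TP"))
  ann <- list(
    q = list(cds = c("cd1", "cd2"), superfamilies = "cl1"),
    s1 = list(cds = "cd1", superfamilies = "cl1"),
    s2 = list(cds = character(0), superfamilies = character(0)))
  out <- overlap_and_annotation_summary(rpm, thresholds = c(m1 = 1),
                                        annotation = ann)
  fr <- out$annotation_fractions$m1
  expect_equal(unname(fr["same_cd"]), 0.5)
  expect_equal(unname(fr["same_superfamily"]), 0.5)
  expect_equal(unname(fr["no_cd"]), 0.5)
})

test_that("label files round-trip", {
  lb <- toy_labels()
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_labels(lb, tf)
  lb2 <- read_labels(tf)
  expect_equal(as.data.frame(lb2), as.data.frame(lb))
})
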