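#' Read a benchmark label table
#'
#' @param path TSV with columns `id`, `family`, `superfamily`, `fold`.
#' @return A `benchmark_labels` data.frame keyed by id; the
#'   family-to-superfamily and superfamily-to-fold maps must be functions
#'   (checked).
#' @export
read_labels <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  benchmark_labels(df)
}

#' Construct benchmark labels
#'
#' @param df data.frame with columns `id`, `family`, `superfamily`, `fold`.
#' @return A `benchmark_labels` object.
#' @export
benchmark_labels <- function(df) {
  stopifnot(all(c("id", "family", "superfamily", "fold") %in% names(df)))
  if (anyDuplicated(df$id)) stop("duplicate sequence ids in labels")
  chk <- function(child, parent, what) {
    tab <- unique(df[, c(child, parent)])
    if (anyDuplicated(tab[[child]])) {
      stop("inconsistent hierarchy: a ", child, " maps to multiple ", what)
    }
  }
  chk("family", "superfamily", "superfamilies")
  chk("superfamily", "fold", "folds")
  rownames(df) <- df$id
  structure(df, class = c("benchmark_labels", "data.frame"))
}

#' Write benchmark labels as TSV
#'
#' @param labels A `benchmark_labels`.
#' @param path Output path.
#' @export
write_labels <- function(labels, path) {
  write.table(as.data.frame(labels), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Classify a query-subject pair against SCOP-style labels
#'
#' Same id: self (excluded from scoring). Same superfamily: homolog (TP).
#' Different fold: non-homolog (FP). Same fold but different superfamily:
#' ignored, since homology cannot be established either way.
#'
#' @param labels A `benchmark_labels`.
#' @param query_id,subject_id Sequence ids present in `labels`.
#' @return One of `"self"`, `"TP"`, `"FP"`, `"ignored"`.
#' @export
label_pair <- function(labels, query_id, subject_id) {
  if (!query_id %in% labels$id) stop("unknown id: ", query_id)
  if (!subject_id %in% labels$id) stop("unknown id: ", subject_id)
  if (query_id == subject_id) return("self")
  q <- labels[query_id, ]
  s <- labels[subject_id, ]
  if (q$superfamily == s$superfamily) return("TP")
  if (q$fold != s$fold) return("FP")
  "ignored"
}

#' Pool and label ranked search results
#'
#' Labels each (query, subject) pair, removes self hits and ignored pairs,
#' and sorts by E-value ascending with deterministic tie-breaking (bit
#' score descending, then query id, then subject id).
#'
#' @param results data.frame with columns `qseqid`, `sseqid`, `evalue` and
#'   optionally `bitscore`.
#' @param labels A `benchmark_labels`.
#' @param keep_ignored Keep rows labeled `ignored` (default FALSE).
#' @return A `ranked_results` data.frame with an added `label` column.
#' @export
pool_results <- function(results, labels, keep_ignored = FALSE) {
  if (nrow(results) == 0) {
    out <- cbind(results, label = character(0))
  } else {
    lab <- vapply(seq_len(nrow(results)), function(i) {
      label_pair(labels, results$qseqid[i], results$sseqid[i])
    }, "")
    out <- results
    out$label <- lab
    out <- out[out$label != "self", , drop = FALSE]
    if (!keep_ignored) out <- out[out$label != "ignored", , drop = FALSE]
    bs <- if ("bitscore" %in% names(out)) -out$bitscore else 0
    out <- out[order(out$evalue, bs, out$qseqid, out$sseqid), , drop = FALSE]
    rownames(out) <- NULL
  }
  structure(out, class = c("ranked_results", "data.frame"))
}

#' Pooled ROC_n score
#'
#' Normalized area under the ROC curve up to n false positives:
#' \deqn{ROC_n = \frac{1}{nT} \sum_{i=1}^{n} t_i}
#' where \eqn{t_i} is the number of true positives ranked above the i-th
#' false positive and T the number of homologous pairs. When the list
#' holds fewer than n false positives the count of all listed true
#' positives stands in for the missing ranks (truncated-area convention,
#' reported in the result). The standard error is estimated by a seeded
#' bootstrap over queries.
#'
#' @param results A `ranked_results` (self and ignored entries already
#'   removed) or data.frame with columns `label` and, for the bootstrap,
#'   `qseqid`.
#' @param n Number of false positives to integrate over.
#' @param total_positives T, the number of homologous pairs attainable.
#' @param bootstrap Number of query-level bootstrap resamples for the
#'   standard error (default 0 = skip).
#' @param seed Seed for the bootstrap.
#' @return List with `score`, `se` (NA unless bootstrapped), `n_fp_seen`,
#'   `truncated`.
#' @export
roc_n <- function(results, n, total_positives, bootstrap = 0, seed = 1) {
  stopifnot(n >= 1, total_positives >= 1)
  if (nrow(results) == 0) stop("empty result list")
  stopifnot(all(results$label %in% c("TP", "FP")))
  score_of <- function(lab) {
    is_fp <- lab == "FP"
    tp_above <- cumsum(lab == "TP")
    t_i <- tp_above[is_fp]
    nf <- length(t_i)
    if (nf < n) t_i <- c(t_i, rep(sum(lab == "TP"), n - nf))
    sum(t_i[seq_len(n)]) / (n * total_positives)
  }
  sc <- score_of(results$label)
  se <- NA_real_
  if (bootstrap > 0) {
    if (!"qseqid" %in% names(results)) stop("bootstrap needs a qseqid column")
    qs <- unique(results$qseqid)
    idx_by_q <- split(seq_len(nrow(results)), results$qseqid)
    set.seed(seed)
    reps <- vapply(seq_len(bootstrap), function(b) {
      pick <- sample(qs, length(qs), replace = TRUE)
      rows <- unlist(idx_by_q[pick], use.names = FALSE)
      sub <- results[sort(rows), , drop = FALSE]
      if (nrow(sub) == 0) return(NA_real_)
      score_of(sub$label)
    }, 0)
    se <- sd(reps, na.rm = TRUE)
  }
  list(score = min(1, sc), se = se,
       n_fp_seen = sum(results$label == "FP"),
       truncated = sum(results$label == "FP") < n)
}

#' Per-query ROC_5 scores and exceedance curve
#'
#' Appends five synthetic false positives to the end of each query's
#' ranked list (so a ROC score over five false positives is always
#' defined), computes each query's ROC_5, and reports the fraction of
#' queries whose score exceeds each threshold on a grid.
#'
#' @param per_query Named list: per query, a character vector of labels
#'   (`"TP"`/`"FP"`) in rank order (self/ignored already removed).
#' @param total_positives Named numeric: attainable homolog count T_q per
#'   query. Queries with T_q = 0 are dropped with a warning (mirrors the
#'   removal of singleton-superfamily queries).
#' @param grid Thresholds for the exceedance curve (default 0.1 ... 0.9).
#' @return List with `scores` (named per query) and `exceedance`
#'   (data.frame threshold / fraction).
#' @export
per_query_roc5 <- function(per_query, total_positives,
                           grid = seq(0.1, 0.9, by = 0.1)) {
  keep <- names(per_query)[total_positives[names(per_query)] > 0]
  if (length(keep) < length(per_query)) {
    warning(length(per_query) - length(keep),
            " query(ies) with no attainable homolog excluded")
  }
  scores <- vapply(keep, function(q) {
    lab <- c(per_query[[q]], rep("FP", 5L))
    df <- data.frame(label = lab)
    roc_n(df, n = 5, total_positives = total_positives[[q]])$score
  }, 0)
  exceed <- vapply(grid, function(v) mean(scores > v), 0)
  list(scores = scores,
       exceedance = data.frame(threshold = grid, fraction = exceed))
}

#' Alignment sensitivity and precision against a reference
#'
#' For a test alignment N and reference alignment S, both as sets of
#' residue-index pairs: sensitivity = |N intersect S| / |S|, precision =
#' |N intersect S| / |N|.
#'
#' @param test_pairs,reference_pairs Two-column matrices of aligned index
#'   pairs (any consistent indexing; compared as exact pairs).
#' @return List with `sensitivity` and `precision`.
#' @export
alignment_quality <- function(test_pairs, reference_pairs) {
  if (is.null(reference_pairs) || nrow(reference_pairs) == 0) {
    stop("empty reference alignment")
  }
  key <- function(m) paste(m[, 1], m[, 2], sep = ":")
  N <- unique(key(test_pairs))
  S <- unique(key(reference_pairs))
  inter <- length(intersect(N, S))
  list(sensitivity = inter / length(S),
       precision = if (length(N) == 0) 0 else inter / length(N))
}

#' Bin alignment-quality results by reference sequence identity
#'
#' @param quality data.frame with columns `identity` (reference-alignment
#'   fractional identity), `sensitivity`, `precision`.
#' @param breaks Identity bin edges (default 0 to 1 by 0.05).
#' @return data.frame of per-bin mean sensitivity/precision and counts.
#' @export
bin_alignment_quality <- function(quality, breaks = seq(0, 1, by = 0.05)) {
  b <- cut(quality$identity, breaks, include.lowest = TRUE)
  out <- do.call(rbind, lapply(split(quality, b), function(d) {
    if (nrow(d) == 0) return(NULL)
    data.frame(bin = as.character(b[rownames(quality) %in% rownames(d)][1]),
               n = nrow(d),
               sensitivity = mean(d$sensitivity),
               precision = mean(d$precision))
  }))
  rownames(out) <- NULL
  out
}

#' Nominal E-value calibration curve
#'
#' For each threshold x on a grid, the mean number of false positive hits
#' per query with nominal E-value at or below x: a monotone non-decreasing
#' step curve that exposes how the reported E-values relate to realised
#' error counts.
#'
#' @param results Labeled results data.frame (`qseqid`, `evalue`, `label`).
#' @param n_queries Number of queries averaged over (defaults to the
#'   distinct `qseqid` count; pass the full query-set size when some
#'   queries returned nothing).
#' @param grid Thresholds x (default log-spaced 1e-10 ... 10).
#' @return data.frame with columns `x` and `mean_fp`.
#' @export
evalue_calibration <- function(results, n_queries = NULL,
                               grid = 10^seq(-10, 1, by = 0.25)) {
  if (is.null(n_queries)) n_queries <- length(unique(results$qseqid))
  stopifnot(n_queries >= 1)
  fp_e <- sort(results$evalue[results$label == "FP"])
  mean_fp <- vapply(grid, function(x) sum(fp_e <= x) / n_queries, 0)
  data.frame(x = grid, mean_fp = mean_fp)
}

#' Solve the calibration curve for a target mean false-positive count
#'
#' Returns the smallest nominal E-value threshold at which the mean number
#' of false positives per query reaches `target` — the crossing point of
#' the step curve, equal to the E-value of the ceiling(target * n_queries)-th
#' ranked false positive (the construction used to put different methods'
#' thresholds on a common error footing). When the target is attainable
#' exactly, the mean at the returned x equals the target.
#'
#' @param results Labeled results (`qseqid`, `evalue`, `label`).
#' @param target Mean FP count per query (e.g. 0.3).
#' @param n_queries As in [evalue_calibration()].
#' @return The threshold x; `Inf` when the curve never reaches `target`.
#' @export
calibration_threshold <- function(results, target, n_queries = NULL) {
  if (is.null(n_queries)) n_queries <- length(unique(results$qseqid))
  fp_e <- sort(results$evalue[results$label == "FP"])
  k <- ceiling(target * n_queries)
  if (k < 1) k <- 1
  if (length(fp_e) < k) return(Inf)
  fp_e[k]
}

#' Overlap and annotation summary of true-positive sets across methods
#'
#' Per method, the set of true-positive (query, subject) pairs returned at
#' that method's E-value cutoff; all Venn region counts over those sets;
#' and, when an annotation map is given, the fraction of each method's
#' true positives whose query and subject share a domain annotation, share
#' a domain superfamily, are annotated with different superfamilies, or
#' where either partner has no domain association. The last two categories
#' need not complement the first two, since a domain may belong to no
#' superfamily.
#'
#' @param results_per_method Named list of labeled results data.frames
#'   (`qseqid`, `sseqid`, `evalue`, `label`).
#' @param thresholds Named numeric E-value cutoffs, one per method.
#' @param annotation Optional named list: per sequence id, a list with
#'   `cds` (character vector of associated profile ids) and `superfamilies`
#'   (character vector of their superfamily ids).
#' @return List with `tp_sets` (per method, character keys "q|s"),
#'   `regions` (data.frame of Venn region membership counts; counts sum to
#'   the union size) and `annotation_fractions` (per method, or NULL).
#' @export
overlap_and_annotation_summary <- function(results_per_method, thresholds,
                                           annotation = NULL) {
  stopifnot(length(results_per_method) >= 1,
            all(names(results_per_method) %in% names(thresholds) |
                  length(thresholds) == length(results_per_method)))
  methods <- names(results_per_method)
  tp_sets <- lapply(methods, function(m) {
    r <- results_per_method[[m]]
    r <- r[r$label == "TP" & r$evalue <= thresholds[[m]], , drop = FALSE]
    unique(paste(r$qseqid, r$sseqid, sep = "|"))
  })
  names(tp_sets) <- methods
  univ <- unique(unlist(tp_sets))
  membership <- vapply(methods, function(m) univ %in% tp_sets[[m]],
                       logical(length(univ)))
  if (length(univ) == 1L) membership <- matrix(membership, nrow = 1,
                                               dimnames = list(NULL, methods))
  region <- apply(membership, 1, function(z) paste(methods[z], collapse = "&"))
  regions <- as.data.frame(table(region), stringsAsFactors = FALSE)
  names(regions) <- c("region", "count")
  ann_frac <- NULL
  if (!is.null(annotation)) {
    frac_of <- function(pairs) {
      if (length(pairs) == 0) {
        return(c(same_cd = NA, same_superfamily = NA,
                 different_superfamilies = NA, no_cd = NA))
      }
      cats <- vapply(pairs, function(p) {
        ids <- strsplit(p, "\\|")[[1]]
        a <- annotation[[ids[1]]]
        b <- annotation[[ids[2]]]
        no_a <- is.null(a) || length(a$cds) == 0
        no_b <- is.null(b) || length(b$cds) == 0
        c(same_cd = !no_a && !no_b && length(intersect(a$cds, b$cds)) > 0,
          same_superfamily = !no_a && !no_b &&
            length(intersect(a$superfamilies, b$superfamilies)) > 0,
          different_superfamilies = !no_a && !no_b &&
            length(intersect(a$superfamilies, b$superfamilies)) == 0,
          no_cd = no_a || no_b)
      }, logical(4))
      rowMeans(cats)
    }
    ann_frac <- lapply(tp_sets, frac_of)
  }
  list(tp_sets = tp_sets, regions = regions,
       annotation_fractions = ann_frac)
}

#' Annotate sequences with domain associations
#'
#' Runs the domain search for each sequence at the annotation threshold
#' (default E <= 0.01) and records the associated profile ids and their
#' superfamilies, the map consumed by
#' [overlap_and_annotation_summary()].
#'
#' @param seqs Named character vector of sequences.
#' @param library A `profile_library` (with `superfamily_of` for
#'   superfamily annotation).
#' @param matrix An `aa_matrix`.
#' @param evalue_cutoff Association threshold (default 0.01).
#' @param ... Passed to [search_domains()].
#' @return Named list per id: `cds`, `superfamilies`.
#' @export
annotate_sequences <- function(seqs, library, matrix = read_matrix(),
                               evalue_cutoff = 0.01, ...) {
  out <- lapply(seqs, function(s) {
    hits <- search_domains(s, library, matrix,
                           inclusion_evalue = evalue_cutoff, ...)
    cds <- unique(vapply(hits, `[[`, "", "profile_id"))
    sfs <- unique(unname(library$superfamily_of[cds]))
    list(cds = cds, superfamilies = sfs[!is.na(sfs)])
  })
  names(out) <- names(seqs)
  out
}
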