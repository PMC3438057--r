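#' Configuration for the synthetic benchmark simulator
#'
#' Defaults describe the scaled-down benchmark used throughout the
#' package's tests: 2 folds x 2 superfamilies x 2 families x 5 sequences
#' of length 80, with per-level divergences (expected substitution events
#' per site on the branch from the parent level) calibrated so that
#' sequences from different families of the same superfamily share roughly
#' 15-25% identity.
#'
#' @param seed Integer seed driving all randomness.
#' @param n_folds,superfamilies_per_fold,families_per_superfamily,seqs_per_family
#'   Hierarchy sizes (all >= 1).
#' @param seq_length Root sequence length (single integer or range to
#'   sample uniformly).
#' @param divergence Named numeric: expected substitution events/site on
#'   the `superfamily`, `family` and `leaf` branches.
#' @param indel_rate Expected indel events per site per branch.
#' @param background Residue composition of root sequences and insertions.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1, n_folds = 2, superfamilies_per_fold = 2,
                       families_per_superfamily = 2, seqs_per_family = 5,
                       seq_length = 80,
                       divergence = c(superfamily = 1.5, family = 1.0,
                                      leaf = 0.45),
                       indel_rate = 0.01,
                       background = read_matrix()$background) {
  stopifnot(n_folds >= 1, superfamilies_per_fold >= 1,
            families_per_superfamily >= 1, seqs_per_family >= 1,
            all(seq_length >= 5), all(divergence >= 0), indel_rate >= 0,
            abs(sum(background) - 1) < 1e-6)
  structure(list(seed = as.integer(seed), n_folds = n_folds,
                 superfamilies_per_fold = superfamilies_per_fold,
                 families_per_superfamily = families_per_superfamily,
                 seqs_per_family = seqs_per_family, seq_length = seq_length,
                 divergence = divergence, indel_rate = indel_rate,
                 background = background),
            class = "sim_config")
}

# residue-substitution process: replacement residue drawn from the
# matrix-conditional distribution C[i, j] = q_ij / p_i (rows sum to 1
# because the target frequencies' marginals equal the background), so the
# simulator's notion of relatedness is the one the scoring model assumes.
.conditional_matrix <- function(matrix) {
  C <- matrix$target_freqs / matrix$background
  C / rowSums(C)
}

# evolve a sequence along one branch. `anc` maps each position to its
# root-coordinate (NA for inserted positions). Returns seq indices + anc.
.evolve <- function(idx, anc, divergence, indel_rate, C, background) {
  L <- length(idx)
  nev <- rpois(L, divergence)
  for (i in which(nev > 0)) {
    for (k in seq_len(nev[i])) {
      idx[i] <- sample.int(20L, 1L, prob = C[idx[i], ])
    }
  }
  n_indel <- rpois(1, indel_rate * L)
  for (e in seq_len(n_indel)) {
    len <- 1L + rgeom(1L, 0.5)
    if (runif(1) < 0.5) { # deletion
      if (length(idx) <= len + 2L) next
      at <- sample.int(length(idx) - len, 1L)
      drop <- at:(at + len - 1L)
      idx <- idx[-drop]
      anc <- anc[-drop]
    } else { # insertion
      at <- sample.int(length(idx) + 1L, 1L)
      ins <- sample.int(20L, len, replace = TRUE, prob = background)
      idx <- append(idx, ins, after = at - 1L)
      anc <- append(anc, rep(NA_integer_, len), after = at - 1L)
    }
  }
  list(idx = idx, anc = anc)
}

.idx_to_seq <- function(idx) paste(aa_alphabet()[idx], collapse = "")

#' Simulate a fold/superfamily/family-structured benchmark
#'
#' Hierarchical ancestor simulation: an independent random root per fold
#' (so different folds are unrelated), then superfamily, family and leaf
#' sequences derived by matrix-conditional substitutions plus
#' geometric-length indels. Every sequence carries a map from its positions
#' to its fold root's coordinates, from which true pairwise reference
#' alignments follow. Deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @return A `sim_benchmark`: `db` (named residue strings), `labels`
#'   (`benchmark_labels`), `anc` (per-sequence root-coordinate maps),
#'   `family_ancestors` (per family: `idx`, `anc`), `config`.
#' @export
simulate_benchmark <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  C <- NULL
  mat <- read_matrix()
  C <- .conditional_matrix(mat)
  bg <- config$background
  db <- character(0)
  anc_maps <- list()
  fam_anc <- list()
  lab <- list()
  for (fd in seq_len(config$n_folds)) {
    L <- if (length(config$seq_length) > 1) {
      sample(config$seq_length[1]:config$seq_length[2], 1L)
    } else config$seq_length
    root <- sample.int(20L, L, replace = TRUE, prob = bg)
    root_anc <- seq_len(L)
    fold_id <- sprintf("f%d", fd)
    for (sf in seq_len(config$superfamilies_per_fold)) {
      sfa <- .evolve(root, root_anc, config$divergence[["superfamily"]],
                     config$indel_rate, C, bg)
      sf_id <- sprintf("%s.s%d", fold_id, sf)
      for (fm in seq_len(config$families_per_superfamily)) {
        fma <- .evolve(sfa$idx, sfa$anc, config$divergence[["family"]],
                       config$indel_rate, C, bg)
        fam_id <- sprintf("%s.%s", sf_id, letters[fm])
        fam_anc[[fam_id]] <- fma
        for (sq in seq_len(config$seqs_per_family)) {
          leaf <- .evolve(fma$idx, fma$anc, config$divergence[["leaf"]],
                          config$indel_rate, C, bg)
          id <- sprintf("%s.%d", fam_id, sq)
          db[[id]] <- .idx_to_seq(leaf$idx)
          anc_maps[[id]] <- leaf$anc
          lab[[id]] <- data.frame(id = id, family = fam_id,
                                  superfamily = sf_id, fold = fold_id)
        }
      }
    }
  }
  structure(list(db = db,
                 labels = benchmark_labels(do.call(rbind, lab)),
                 anc = anc_maps, family_ancestors = fam_anc,
                 config = config),
            class = "sim_benchmark")
}

#' @export
print.sim_benchmark <- function(x, ...) {
  cat("Synthetic benchmark:", length(x$db), "sequences,",
      length(unique(x$labels$fold)), "folds,",
      length(unique(x$labels$superfamily)), "superfamilies,",
      length(unique(x$labels$family)), "families\n")
  invisible(x)
}

#' True reference alignment between two simulated sequences
#'
#' Residue pairs descending from the same root coordinate of their shared
#' fold ancestor. Sequences from different folds share no ancestry and
#' yield an empty reference.
#'
#' @param sim A `sim_benchmark`.
#' @param id_a,id_b Sequence ids.
#' @return Two-column matrix of 0-based aligned (a_pos, b_pos) pairs,
#'   strictly increasing in both coordinates.
#' @export
reference_alignment <- function(sim, id_a, id_b) {
  a <- sim$anc[[id_a]]
  b <- sim$anc[[id_b]]
  if (is.null(a) || is.null(b)) stop("unknown sequence id")
  if (sim$labels[id_a, "fold"] != sim$labels[id_b, "fold"]) {
    return(matrix(0L, 0, 2))
  }
  common <- intersect(a[!is.na(a)], b[!is.na(b)])
  if (length(common) == 0) return(matrix(0L, 0, 2))
  pa <- match(common, a) - 1L
  pb <- match(common, b) - 1L
  ord <- order(pa)
  cbind(pa[ord], pb[ord])
}

#' Simulate held-out family members
#'
#' Draws additional leaves from a family's stored ancestor (they share the
#' ancestry of the database members but are not in the database), used for
#' building profiles and held-out queries. Randomness continues from the
#' current RNG state; seed externally for reproducibility.
#'
#' @param sim A `sim_benchmark`.
#' @param family_id One of the simulated family ids.
#' @param n Number of members.
#' @param divergence Branch length from the family ancestor (defaults to
#'   the config's leaf divergence).
#' @return List with `seqs` (named residue strings), `anc_family`
#'   (per-member maps to family-ancestor coordinates).
#' @export
simulate_family_members <- function(sim, family_id, n,
                                    divergence = NULL) {
  fa <- sim$family_ancestors[[family_id]]
  if (is.null(fa)) stop("unknown family: ", family_id)
  if (is.null(divergence)) divergence <- sim$config$divergence[["leaf"]]
  mat <- read_matrix()
  C <- .conditional_matrix(mat)
  seqs <- character(0)
  anc <- list()
  for (k in seq_len(n)) {
    lf <- .evolve(fa$idx, seq_along(fa$idx), divergence,
                  sim$config$indel_rate, C, sim$config$background)
    id <- sprintf("%s.held%d", family_id, k)
    seqs[[id]] <- .idx_to_seq(lf$idx)
    anc[[id]] <- lf$anc
  }
  list(seqs = seqs, anc_family = anc)
}

#' Simulate a conserved-domain profile library for the benchmark
#'
#' One profile per simulated family, built from held-out members aligned
#' on the family ancestor's coordinates (member insertions relative to the
#' ancestor are dropped; ancestor positions missing from a member become
#' gaps), via [build_profile()]. Records each profile's superfamily.
#'
#' @param sim A `sim_benchmark`.
#' @param members_per_profile Held-out members per family (default 12;
#'   enough diversity for profiles to pass the max-observations >= 6
#'   filter).
#' @param member_divergence Branch length of held-out members from the
#'   family ancestor (default 1.2, a broader family sample than the
#'   database leaves, emulating the diversity of curated domain
#'   alignments).
#' @param matrix An `aa_matrix`.
#' @return A `profile_library` with `superfamily_of` filled in.
#' @export
simulate_profile_library <- function(sim, members_per_profile = 12,
                                     member_divergence = 1.2,
                                     matrix = read_matrix()) {
  fams <- names(sim$family_ancestors)
  profiles <- list()
  superfamily_of <- character(0)
  for (fam in fams) {
    mem <- simulate_family_members(sim, fam, members_per_profile,
                                   divergence = member_divergence)
    La <- length(sim$family_ancestors[[fam]]$idx)
    rows <- vapply(names(mem$seqs), function(id) {
      res <- strsplit(mem$seqs[[id]], "")[[1]]
      anc <- mem$anc_family[[id]]
      row <- rep("-", La)
      keep <- !is.na(anc)
      row[anc[keep]] <- res[keep]
      paste(row, collapse = "")
    }, "")
    profiles[[fam]] <- build_profile(rows, matrix, id = fam,
                                     description = paste("simulated family", fam))
    sf <- sim$labels$superfamily[match(fam, sim$labels$family)]
    superfamily_of[fam] <- sf
  }
  profile_library(profiles, superfamily_of)
}

#' Write benchmark fixtures to a directory
#'
#' Emits `db.fasta`, `labels.tsv`, `lib.dpl` and `refs.jsonl` (reference
#' alignments for all same-family pairs).
#'
#' @param sim A `sim_benchmark`.
#' @param library A `profile_library` for the benchmark.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the output paths.
#' @export
write_benchmark <- function(sim, library, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- file.path
  write_fasta(sim$db, fp(out_dir, "db.fasta"))
  write_labels(sim$labels, fp(out_dir, "labels.tsv"))
  write_library(library, fp(out_dir, "lib.dpl"))
  con <- file(fp(out_dir, "refs.jsonl"), "w")
  ids <- names(sim$db)
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (j <= i) next
      if (sim$labels[ids[i], "family"] != sim$labels[ids[j], "family"]) next
      pr <- reference_alignment(sim, ids[i], ids[j])
      writeLines(jsonlite::toJSON(
        list(a = ids[i], b = ids[j],
             pairs = unname(apply(pr, 1, c, simplify = FALSE))),
        auto_unbox = TRUE), con)
    }
  }
  close(con)
  invisible(fp(out_dir, c("db.fasta", "labels.tsv", "lib.dpl", "refs.jsonl")))
}
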