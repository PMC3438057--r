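#' Position-based (Henikoff) sequence weights for an MSA
#'
#' Classic position-based weighting: in each column with at least two
#' distinct residue types, a sequence carrying residue type t receives
#' 1/(r * s) where r is the number of distinct types in the column and s the
#' number of sequences sharing type t. Gap characters and ambiguity codes
#' carry no weight. Per-sequence totals are normalised to sum to 1; if no
#' column has two distinct types (e.g. identical sequences) the weights are
#' uniform.
#'
#' @param msa Character vector of equal-length aligned rows (`-` gaps).
#' @return Numeric vector of positive weights summing to 1, one per row.
#' @export
sequence_weights <- function(msa) {
  mat <- .msa_matrix(msa)
  ns <- nrow(mat)
  w <- numeric(ns)
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    keep <- !is.na(.aa_index(col))
    types <- unique(col[keep])
    r <- length(types)
    if (r < 2L) next
    counts <- table(col[keep])
    w[keep] <- w[keep] + 1 / (r * as.numeric(counts[col[keep]]))
  }
  if (sum(w) <= 0) return(rep(1 / ns, ns))
  w / sum(w)
}

# Expected number of distinct residue types among N independent draws from
# `background`; continuous in N.
.expected_distinct <- function(N, background) {
  vapply(N, function(n) sum(1 - (1 - background)^n), 0)
}

# Invert the expected-distinct curve: observation count N with
# E[distinct | N] = d. Monotone root-find on the closed form.
.invert_distinct <- function(d, background) {
  if (d <= 1) return(1)
  dmax <- sum(background > 0)
  if (d >= dmax) return(Inf)
  f <- function(n) .expected_distinct(n, background) - d
  hi <- 2
  while (f(hi) < 0 && hi < 1e8) hi <- hi * 2
  uniroot(f, c(1, hi), tol = 1e-8)$root
}

#' Effective number of independent observations per MSA column
#'
#' For each column c, takes the set of sequences with a residue at c and
#' averages, over every column where at least one of those sequences has a
#' residue, the number of distinct residue types they display. That mean
#' distinct-residue count is mapped to an observation number by inverting
#' the expected-distinct-types curve E[distinct | N draws from background],
#' and clamped to [1, number of distinct sequences] (duplicate rows carry
#' no independent information). A column of a single-sequence alignment
#' therefore scores exactly 1.
#'
#' @param msa Character vector of aligned rows.
#' @param background Length-20 background probabilities (defaults to the
#'   shipped matrix background).
#' @return Numeric vector (one value >= 1 per alignment column).
#' @export
effective_observations <- function(msa,
                                   background = read_matrix()$background) {
  mat <- .msa_matrix(msa)
  ns <- nrow(mat)
  nc <- ncol(mat)
  # duplicated rows carry no independent information: they cannot raise the
  # observation count (cap at the number of distinct rows)
  n_distinct <- nrow(unique(mat))
  isres <- matrix(!is.na(.aa_index(mat)), nrow = ns)
  # distinct residue counts for a sequence subset are reused across columns
  # sharing the same subset
  subset_key <- apply(isres, 2, function(z) paste(which(z), collapse = ","))
  mean_distinct <- setNames(numeric(0), character(0))
  out <- numeric(nc)
  for (j in seq_len(nc)) {
    key <- subset_key[j]
    if (!nzchar(key)) { out[j] <- 1; next } # gap-only column
    if (is.na(mean_distinct[key])) {
      rows <- which(isres[, j])
      sub <- mat[rows, , drop = FALSE]
      subres <- isres[rows, , drop = FALSE]
      cols <- which(colSums(subres) > 0)
      d <- vapply(cols, function(cc) {
        length(unique(sub[subres[, cc], cc]))
      }, 0L)
      mean_distinct[key] <- mean(d)
    }
    nobs <- .invert_distinct(mean_distinct[key], background)
    out[j] <- min(max(1, nobs), n_distinct)
  }
  out
}

#' Build a conserved-domain profile from a multiple sequence alignment
#'
#' Per-column weighted observed residue frequencies (sequence weights from
#' [sequence_weights()], gap and ambiguity characters contributing zero
#' counts) plus the per-column effective number of independent observations.
#' Columns containing only gaps get an all-zero frequency row and are
#' skipped during alignment.
#'
#' @param msa Character vector of aligned rows (first row may be regarded as
#'   the master sequence; column indexing is over all alignment columns).
#' @param matrix An `aa_matrix` (for its background); default shipped
#'   BLOSUM62.
#' @param id Profile identifier.
#' @param description Free-text description.
#' @return A `domain_profile`: list with `id`, `length`, `freqs`
#'   (length x 20, rows summing to 1 or all zero), `n_obs` (>= 1),
#'   `consensus`, `description`.
#' @export
build_profile <- function(msa, matrix = read_matrix(), id = "profile",
                          description = "") {
  mat <- .msa_matrix(msa)
  w <- sequence_weights(msa)
  idx <- matrix(.aa_index(mat), nrow = nrow(mat))
  nc <- ncol(mat)
  freqs <- matrix(0, nrow = nc, ncol = 20,
                  dimnames = list(NULL, aa_alphabet()))
  for (j in seq_len(nc)) {
    rows <- which(!is.na(idx[, j]))
    if (length(rows) == 0L) next
    tal <- numeric(20)
    for (r in rows) tal[idx[r, j]] <- tal[idx[r, j]] + w[r]
    freqs[j, ] <- tal / sum(tal)
  }
  if (all(rowSums(freqs) == 0)) stop("MSA has no non-gap columns")
  n_obs <- effective_observations(msa, matrix$background)
  consensus <- vapply(seq_len(nc), function(j) {
    if (sum(freqs[j, ]) == 0) "-" else aa_alphabet()[which.max(freqs[j, ])]
  }, "")
  structure(list(id = id, length = nc, freqs = freqs, n_obs = n_obs,
                 consensus = paste(consensus, collapse = ""),
                 description = description),
            class = "domain_profile")
}

#' @export
print.domain_profile <- function(x, ...) {
  cat("Domain profile", x$id, "-", x$length, "columns, max n_obs",
      format(max(x$n_obs), digits = 4), "\n")
  cat("  consensus:", x$consensus, "\n")
  invisible(x)
}

#' Assemble a profile library
#'
#' @param profiles List of `domain_profile` objects (unique ids).
#' @param superfamily_of Optional named character vector mapping profile id
#'   to a superfamily id (used by annotation summaries).
#' @return A `profile_library`.
#' @export
profile_library <- function(profiles, superfamily_of = NULL) {
  ids <- vapply(profiles, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate profile ids in library")
  names(profiles) <- ids
  structure(list(profiles = profiles, superfamily_of = superfamily_of),
            class = "profile_library")
}

#' @export
print.profile_library <- function(x, ...) {
  cat("Profile library:", length(x$profiles), "profiles\n")
  invisible(x)
}

#' @export
length.profile_library <- function(x) length(x$profiles)

#' Write a profile library in the package's structured-text format
#'
#' One document per profile; frequencies and observation counts are printed
#' with 9 significant digits, which is the format's precision: a
#' write-read round trip reproduces the printed values bit-exactly.
#'
#' @param library A `profile_library`.
#' @param path Output path (conventional extension `.dpl`).
#' @export
write_library <- function(library, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) cat(..., "\n", file = con, sep = "")
  w("# deltapssm profile library")
  w("format_version 1")
  w("profiles ", length(library$profiles))
  for (p in library$profiles) {
    w("profile ", p$id)
    w("length ", p$length)
    sf <- library$superfamily_of[p$id]
    if (!is.null(sf) && !is.na(sf)) w("superfamily ", sf)
    if (nzchar(p$description)) w("description ", p$description)
    w("nobs ", paste(format(p$n_obs, digits = 9), collapse = " "))
    w("freqs")
    for (i in seq_len(p$length)) {
      w(paste(format(p$freqs[i, ], digits = 9), collapse = " "))
    }
    w("consensus ", p$consensus)
    w("end")
  }
  invisible(path)
}

#' Read a profile library
#'
#' @param path A file written by [write_library()].
#' @return A `profile_library`; an empty file body yields an empty library.
#' @export
read_library <- function(path) {
  lines <- readLines(path)
  ln <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  fail <- function(i, msg) stop("parse error in ", path, " line ", i, ": ", msg)
  profiles <- list()
  superfamily_of <- character(0)
  k <- 1L
  field <- function(i, key) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (tok[1] != key) fail(i, paste0("expected '", key, "', saw '", tok[1], "'"))
    tok[-1]
  }
  while (k <= length(ln)) {
    i <- ln[k]
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (tok[1] %in% c("format_version", "profiles")) { k <- k + 1L; next }
    if (tok[1] != "profile") fail(i, "expected 'profile'")
    id <- tok[2]
    if (is.na(id)) fail(i, "profile with no id")
    k <- k + 1L
    len <- suppressWarnings(as.integer(field(ln[k], "length")[1]))
    k <- k + 1L
    if (is.na(len) || len < 1L) fail(ln[k - 1L], "bad length")
    sf <- NA_character_
    desc <- ""
    repeat {
      t2 <- strsplit(trimws(lines[ln[k]]), "\\s+")[[1]]
      if (t2[1] == "superfamily") { sf <- t2[2]; k <- k + 1L }
      else if (t2[1] == "description") {
        desc <- sub("^\\s*description\\s*", "", lines[ln[k]]); k <- k + 1L
      } else break
    }
    nobs <- suppressWarnings(as.numeric(field(ln[k], "nobs")))
    k <- k + 1L
    if (length(nobs) != len || anyNA(nobs)) fail(ln[k - 1L], "bad nobs vector")
    if (trimws(lines[ln[k]]) != "freqs") fail(ln[k], "expected 'freqs'")
    k <- k + 1L
    freqs <- matrix(0, nrow = len, ncol = 20,
                    dimnames = list(NULL, aa_alphabet()))
    for (r in seq_len(len)) {
      v <- suppressWarnings(as.numeric(strsplit(trimws(lines[ln[k]]), "\\s+")[[1]]))
      if (length(v) != 20L || anyNA(v)) fail(ln[k], "bad frequency row")
      freqs[r, ] <- v
      k <- k + 1L
    }
    consensus <- field(ln[k], "consensus")[1]; k <- k + 1L
    if (trimws(lines[ln[k]]) != "end") fail(ln[k], "expected 'end'")
    k <- k + 1L
    profiles[[id]] <- structure(
      list(id = id, length = len, freqs = freqs, n_obs = nobs,
           consensus = consensus, description = desc),
      class = "domain_profile")
    if (!is.na(sf)) superfamily_of[id] <- sf
  }
  profile_library(profiles,
                  if (length(superfamily_of)) superfamily_of else NULL)
}
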