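Package: deltapssm
Title: Domain-Enhanced PSSM Construction and Protein Database Search
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds position-specific score matrices (PSSMs) for protein
    queries by aligning them to a library of conserved-domain profiles and
    combining the matched profile columns with observation-weighted
    frequencies and data-dependent pseudocounts, then searches protein
    sequence databases with the resulting PSSM under Karlin-Altschul
    statistics. Includes gapped Smith-Waterman profile and sequence search,
    a BLASTP-style fallback for queries without domain matches, ROC-based
    homology-detection benchmarking, alignment sensitivity and precision
    measures, E-value calibration curves, and a seeded simulator of
    fold/superfamily/family-structured benchmark databases and domain
    profile libraries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
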