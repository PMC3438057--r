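---
title: "Domain-enhanced PSSM search: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Domain-enhanced PSSM search: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deltapssm)
```

## The problem and the approach

Remote protein homologs often share too little sequence identity for a
plain substitution-matrix search (BLASTP-style) to separate them from
chance matches. Iterative profile methods gain sensitivity by learning a
position-specific score matrix (PSSM) from intermediate search results,
at the cost of repeated database searches. The approach implemented here
takes a shortcut: curated conserved-domain profiles already summarise
deep family alignments, so a single fast search of a *profile library*
can supply the position-specific information directly. The pipeline is

1. **Domain search** — align the query to every profile in the library
   by gapped local alignment against profile-derived scores and keep the
   statistically significant matches;
2. **PSSM construction** — collapse the matched profile columns onto the
   query template and convert the blended frequencies to integer
   log-odds scores;
3. **Database search** — run a gapped Smith–Waterman search of a protein
   database with the PSSM, reporting E-value-ranked hits.

A query that matches no domain is searched with the plain substitution
matrix; by construction this is *identical* to searching with the PSSM
the pipeline would build from zero domain hits (see "exactness by
construction" below).

## The scoring model

Scores are log-odds ratios. For column $i$ of the PSSM and residue $j$,

$$ s_{ij} = \frac{1}{\lambda_u}\,\ln \frac{Q_{ij}}{p_j}, $$

where $p$ is the background composition, $Q_i$ the column's target
frequencies, and $\lambda_u$ the ungapped Karlin–Altschul parameter of
the underlying substitution matrix, so that PSSM scores live in the same
units as matrix scores.

Column target frequencies come from the data-dependent pseudocount mix

$$ Q_i = \frac{\alpha_i f_i + \beta g_i}{\alpha_i + \beta},\qquad
   g_{ij} \propto \sum_k \frac{f_{ik}}{p_k}\, q_{jk}, $$

with $f_i$ the observed column frequencies, $g_i$ the prior implied by
the matrix's joint target frequencies $q$, $\beta$ the pseudocount
weight (default 10, the classic profile-search constant), and
$\alpha_i$ the column's data weight.

**Observation weighting.** Matched profile columns are not weighted by
their alignment score but by their *effective number of independent
observations* $N_c$ — a per-column diversity measure carried by every
profile. Contributions from distinct profiles at one query position are
summed (curated domain models are treated as independent evidence), the
query residue adds a single observation *only where no profile gives it
positive frequency* (preventing over-representation of the query in
columns that deep family models already cover), and the data weight is
$\alpha_i = N_{c,\mathrm{total}} - 1$: one observation carries no
frequency information beyond the prior.

**Collapse rules.** The query is the template of the implied multiple
alignment: profile columns aligned to residues of the query map onto
those positions, profile columns falling inside insertions relative to
the query are discarded, and if one profile aligns to the same query
position more than once (possible when suboptimal alignments per profile
are requested), only its lowest-E-value alignment contributes there.
Ties are broken by larger raw score, then smaller profile column, making
the collapse deterministic and independent of hit order.

## Statistics

Raw scores get E-values through the Karlin–Altschul formula
$E = K m n e^{-\lambda S}$ with the BLAST-convention length adjustment
(fixed point of $\ell = \ln(K(m-\ell)(n-N\ell))/H$). Gapped parameters
for the default costs (open 11, extend 1) are the standard published
constants $(\lambda_g, K_g, H_g) = (0.267, 0.041, 0.14)$, stored in the
matrix file rather than estimated by simulation. Before search, every
PSSM is rescaled so that its own ungapped $\lambda$ (computed against
the background with positions weighted uniformly) equals the matrix's
$\lambda_u$: because $\lambda(cS) = \lambda(S)/c$, the multiplier is
obtained in closed form as $c = \lambda_{\mathrm{PSSM}}/\lambda_u$,
well inside the $10^{-4}$ relative tolerance the scaling step targets.
The profile-search stage treats the filtered library as one corpus (its
total column count is the database length for E-values).

## Exactness by construction: the background choice

The shipped matrix file carries BLOSUM62 integer scores together with a
background composition $p$ chosen as the unique solution of
$\sum_j p_j e^{\lambda s_{ij}} = 1$ for every residue $i$ (computed by a
one-dimensional root search on $\lambda$ with $p = A(\lambda)^{-1}\mathbf 1$,
$A(\lambda) = e^{\lambda S}$). This is the composition under which the
*integer* matrix is exactly a log-odds system: the implied target
frequencies $q_{ij} = p_i p_j e^{\lambda s_{ij}}$ are symmetric, sum to
one, and have marginals exactly $p$ ($\lambda = 0.3240$, the matrix's
intrinsic value; the composition is close to the familiar
Robinson–Robinson frequencies, largest component difference about
0.016). The payoff is a chain of exact identities:

* a query-only PSSM (no domain hits) has float scores *equal* to the
  matrix rows, its scaling multiplier is exactly 1, and its integer rows
  equal the matrix rows — so the fallback search and the query-only PSSM
  search agree hit for hit, exactly, not merely approximately;
* the pseudocount prior maps the background to itself, so positions with
  no information score zero against everything;
* the simulator's substitution process (below) uses the conditional
  $q_{ij}/p_i$, whose rows are exact probability distributions.

Had we shipped an external composition instead, each identity would hold
only to within rounding, and the query-only limit would depend on
fragile half-integer rounding behaviour.

## Profile representation

A domain profile stores, per column, weighted observed residue
frequencies and the effective observation count $N_c$. Profiles built
from alignments use Henikoff position-based sequence weights (computed
over columns with at least two residue types; gaps carry no weight).
$N_c$ is obtained by the distinct-residue inversion: for the sequences
present at a column, the mean number of distinct residue types per
column of their alignment span is mapped through the inverse of
$E[\mathrm{distinct} \mid N \text{ draws from } p] = \sum_i (1-(1-p_i)^N)$,
then clamped to $[1, \text{number of distinct rows}]$ (a duplicated
sequence can never raise the count — this also keeps the count monotone
under duplication). The clamp and the exact span convention are our
choices; the literature this construction follows leaves them open, and
they are deliberately conservative.

Two filters guard PSSM quality, both exposed as parameters:

| parameter | default | meaning |
|---|---|---|
| `min_max_obs` | 6 | profiles whose maximum $N_c$ across columns is below 6 model too-narrow families and are skipped before alignment |
| `inclusion_evalue` | 0.05 | domain matches above this E-value are not trusted for PSSM construction |
| `beta` | 10 | pseudocount weight: prior vs observed balance |
| `gap_open`, `gap_extend` | 11, 1 | affine gap costs in both search stages |
| report E-value | 10 | database-search reporting threshold |
| annotation E-value | 0.01 | domain-association threshold for annotation summaries |

## The synthetic benchmark

`simulate_benchmark()` emulates a structural-classification benchmark:
independent random root sequences per *fold* (so cross-fold pairs are
true non-homologs), with *superfamily*, *family* and *leaf* sequences
derived along a fixed hierarchy by matrix-conditional substitutions
(replacement residue drawn $\propto q_{ij}/p_i$, i.e. the relatedness
model the scores assume) plus geometric-length indels (mean 2, rate 0.01
events/site/branch). Defaults: 2 folds × 2 superfamilies × 2 families ×
5 sequences of length 80, branch divergences (1.5, 1.0, 0.45) expected
substitution events per site. These divergences were calibrated once so
that sequences from different families of one superfamily share roughly
15–25% identity over their true alignment — the "twilight zone" where
domain information should matter — and then frozen. Profile libraries
are built from 12 held-out members per family at branch length 1.2
(domain alignments are broader samples of a family than any benchmark
sequence), which reliably puts profiles above the `min_max_obs = 6`
diversity floor.

Every simulated sequence carries a map to its fold root's coordinates,
so true pairwise reference alignments (and hence alignment sensitivity
$|N\cap S|/|S|$ and precision $|N\cap S|/|N|$ against them) come from
the indel history, not from a heuristic re-alignment.

What the simulator does *not* emulate: multi-domain architectures,
composition bias, low-complexity regions, structure-conserving selection
(it is a neutral substitution process), and realistic family-size
imbalance. Passing the benchmark therefore shows the machinery is
correct and that domain profiles help under the model's own notion of
relatedness; it does not certify sensitivity gains on real proteomes.

## Evaluation machinery

Search quality is measured the standard way for structural benchmarks:
a hit is a true positive if query and subject share a superfamily, a
false positive if they lie in different folds, and unscored within a
fold across superfamilies; self-hits are removed. Pooled results sorted
by E-value (ties: bit score, then ids) give the ROC$_n$ score
$\frac{1}{nT}\sum_{i=1}^n t_i$, with $t_i$ the true positives ranked
above the $i$-th false positive and $T$ the attainable homolog count.
When a list holds fewer than $n$ false positives the full TP count
stands in for the missing ranks (truncated-area convention, flagged in
the result). Per-query ROC$_5$ lists are padded with five synthetic
false positives so the score is always defined; standard errors use a
seeded query-level bootstrap (1000 resamples by default) — a documented
substitute for the analytic estimator the benchmark literature cites.
E-value calibration curves report the mean number of false positives per
query with nominal E-value ≤ x; `calibration_threshold()` returns the
crossing point where the mean reaches a target level (e.g. 0.3
FP/query), the construction used to put different methods' thresholds on
a common footing before counting true positives.

## Numerical choices and degenerate inputs

* Score rounding: nearest integer, ties away from zero. A zero target
  frequency maps to the floor score (matrix minimum − 1); with
  $\beta > 0$ this arises only for deliberately pathological inputs.
* Integer scale: 1 (matrix units) by default; `scale = 32` mimics the
  up-scaled integer precision BLAST uses internally.
* Alignment traceback ties prefer diagonal, then the gap consuming a
  query/PSSM row, then the gap consuming a subject/profile column; equal
  end scores resolve to the first cell in row-major order. Identical
  inputs therefore give byte-identical outputs.
* Ambiguity codes (X, B, Z, U, *) score as the background-weighted
  average of the relevant score column and contribute zero counts to
  profiles and collapse (a query position that is an ambiguity code gets
  background target frequencies, i.e. all-zero scores).
* Gap-only profile columns are stored as all-zero rows, dropped from the
  score matrix before alignment (with a column map preserving original
  indices), and skipped during collapse.
* One optimal alignment per profile by default; `max_hsps > 1` returns
  non-overlapping suboptimal alignments by iteratively masking each
  hit's query-range × profile-range block, which is what makes the
  per-column lowest-E dedup rule reachable.
* Coordinates are 0-based half-open internally; user-facing tables are
  1-based inclusive (BLAST tabular convention).

## Problem sizes

The shipped tests and the acceptance script run entirely on generated
data at desk scale: alignment exactness is checked against an
enumeration oracle on hundreds of small random instances (queries ≤ 15,
subjects ≤ 12), statistical identities on thousands of random columns,
and the end-to-end comparison on 20 replicate benchmarks of 40 database
sequences with 8 family profiles and 8 held-out queries each — sizes
chosen so the full validation is a matter of a minute or two on one
core while still exercising every stage of the pipeline.

## Known limitations

* E-value absolute calibration inherits the stored gapped constants; on
  tiny databases E-values are conventional rather than empirical.
* The profile-search stage is exhaustive dynamic programming — exact and
  simple, but not built for libraries beyond a few thousand profiles.
* Cross-profile column weights are summed; other normalisations of
  "proportional to independent observations" are defensible, and the
  constant is exposed so the choice is auditable.
* No low-complexity filtering or composition-based statistics.
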