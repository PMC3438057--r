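#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap local alignment (Gotoh) over a precomputed cell-score matrix.
// cell(i, j) holds the score for pairing row position i with column position
// j; the one kernel therefore serves residue-vs-residue (substitution matrix
// lookups), query-vs-profile (profile-derived scores) and PSSM-vs-subject
// search. A gap of length k costs open + k * extend (BLAST convention: the
// first gapped position costs open + extend).
//
// Traceback is deterministic: ties prefer diagonal, then a gap consuming a
// row ("up"), then a gap consuming a column ("left"); among equal-scoring
// end cells the first in row-major order wins, and a zero-score prefix is
// never extended.
//
// Returns list(score, pairs): pairs is an L x 2 integer matrix of 0-based
// (row_pos, col_pos) aligned pairs, strictly increasing in both coordinates;
// zero rows when the best local score is 0.
// [[Rcpp::export(name = ".sw_align_cells")]]
List sw_align_cells(NumericMatrix cell, double gap_open, double gap_extend) {
  const int n = cell.nrow(), m = cell.ncol();
  const double og = gap_open + gap_extend;
  const double eps = 1e-9;
  // M: best score ending with (i,j) paired; GR: ending with a gap that
  // consumes row i (subject gap, "up"); GC: ending with a gap that consumes
  // column j (query gap, "left"). Indexed 1..n, 1..m with a zero border.
  std::vector<double> M((n + 1) * (m + 1), 0.0),
      GR((n + 1) * (m + 1), R_NegInf), GC((n + 1) * (m + 1), R_NegInf);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };
  for (int j = 0; j <= m; ++j) M[at(0, j)] = 0.0;
  double best = 0.0;
  int bi = -1, bj = -1;
  for (int i = 1; i <= n; ++i) {
    M[at(i, 0)] = 0.0;
    for (int j = 1; j <= m; ++j) {
      double prev = std::max(
          0.0, std::max(std::max(M[at(i - 1, j - 1)], GR[at(i - 1, j - 1)]),
                        GC[at(i - 1, j - 1)]));
      M[at(i, j)] = prev + cell(i - 1, j - 1);
      GR[at(i, j)] = std::max(
          std::max(M[at(i - 1, j)] - og, GR[at(i - 1, j)] - gap_extend),
          GC[at(i - 1, j)] - og);
      GC[at(i, j)] = std::max(
          std::max(M[at(i, j - 1)] - og, GC[at(i, j - 1)] - gap_extend),
          GR[at(i, j - 1)] - og);
      if (M[at(i, j)] > best + eps) { best = M[at(i, j)]; bi = i; bj = j; }
    }
  }
  if (best <= eps) {
    return List::create(_["score"] = 0.0, _["pairs"] = IntegerMatrix(0, 2));
  }
  std::vector<int> qi, qj;
  int i = bi, j = bj, state = 0; // 0 = M, 1 = GR, 2 = GC
  while (i > 0 && j > 0) {
    if (state == 0) {
      qi.push_back(i - 1);
      qj.push_back(j - 1);
      double prev = M[at(i, j)] - cell(i - 1, j - 1);
      if (prev <= eps) break; // started at the zero floor
      double dM = M[at(i - 1, j - 1)], dGR = GR[at(i - 1, j - 1)],
             dGC = GC[at(i - 1, j - 1)];
      if (std::fabs(dM - prev) < eps) state = 0;
      else if (std::fabs(dGR - prev) < eps) state = 1;
      else state = 2;
      (void)dGC;
      --i; --j;
    } else if (state == 1) { // gap consuming row i
      double cur = GR[at(i, j)];
      if (std::fabs(M[at(i - 1, j)] - og - cur) < eps) state = 0;
      else if (std::fabs(GR[at(i - 1, j)] - gap_extend - cur) < eps) state = 1;
      else state = 2;
      --i;
    } else { // gap consuming column j
      double cur = GC[at(i, j)];
      if (std::fabs(M[at(i, j - 1)] - og - cur) < eps) state = 0;
      else if (std::fabs(GC[at(i, j - 1)] - gap_extend - cur) < eps) state = 2;
      else state = 1;
      --j;
    }
  }
  const int L = (int)qi.size();
  IntegerMatrix pairs(L, 2);
  for (int k = 0; k < L; ++k) {
    pairs(k, 0) = qi[L - 1 - k];
    pairs(k, 1) = qj[L - 1 - k];
  }
  return List::create(_["score"] = best, _["pairs"] = pairs);
}
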