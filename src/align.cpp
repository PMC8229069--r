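#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Gotoh semi-global (end-gap-free) alignment of two IUPAC bitmask vectors.
// Two states are scored as a match iff their base-set bitmasks intersect,
// so an ambiguity code is never penalized against a base it contains.
// A gap run of length L costs gap_open + (L-1)*gap_ext; terminal gap runs
// in either sequence are free. Traceback tie-break: diagonal > up (gap in
// reference) > left (gap in sample); for gap-state predecessors: open from
// the match state > open from the other gap state > extension. The end
// cell is chosen, among maximal-score cells on the last row/column, as the
// one consuming the most of both sequences (largest i, then largest j).
//
// Returns the score plus the aligned core as two 1-based index vectors
// (0 = gap); free terminal overhangs are appended by the R wrapper.
// [[Rcpp::export]]
List align_semiglobal_c(IntegerVector am, IntegerVector bm,
                        double match, double mismatch,
                        double gap_open, double gap_ext) {
  const int n = am.size(), m = bm.size();
  const double NEG = -1e18;
  const int W = m + 1;
  std::vector<double> M((n + 1) * W, NEG), X((n + 1) * W, NEG),
      Y((n + 1) * W, NEG);
  auto at = [W](int i, int j) { return i * W + j; };

  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) X[at(i, 0)] = 0.0;  // free leading sample overhang
  for (int j = 1; j <= m; ++j) Y[at(0, j)] = 0.0;  // free leading reference overhang

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = (am[i - 1] & bm[j - 1]) ? match : mismatch;
      double d = std::max(M[at(i - 1, j - 1)],
                          std::max(X[at(i - 1, j - 1)], Y[at(i - 1, j - 1)]));
      M[at(i, j)] = d + s;
      X[at(i, j)] = std::max(
          std::max(M[at(i - 1, j)], Y[at(i - 1, j)]) + gap_open,
          X[at(i - 1, j)] + gap_ext);
      Y[at(i, j)] = std::max(
          std::max(M[at(i, j - 1)], X[at(i, j - 1)]) + gap_open,
          Y[at(i, j - 1)] + gap_ext);
    }
  }

  auto H = [&](int i, int j) {
    return std::max(M[at(i, j)], std::max(X[at(i, j)], Y[at(i, j)]));
  };

  // terminal cell: maximal score over last row and last column, free
  // trailing overhang implied; prefer largest i, then largest j
  int ei = n, ej = m;
  double best = H(n, m);
  for (int i = n; i >= 0; --i)
    if (H(i, m) > best) { best = H(i, m); ei = i; ej = m; }
  for (int j = m; j >= 0; --j)
    if (H(n, j) > best) { best = H(n, j); ei = n; ej = j; }

  // traceback of the aligned core
  std::vector<int> ai, bi;  // 1-based indices, 0 = gap
  int i = ei, j = ej;
  int state;  // 0 = M, 1 = X (up), 2 = Y (left)
  if (M[at(i, j)] >= X[at(i, j)] && M[at(i, j)] >= Y[at(i, j)]) state = 0;
  else if (X[at(i, j)] >= Y[at(i, j)]) state = 1;
  else state = 2;
  if (i == 0 || j == 0) state = -1;  // empty core (degenerate)

  while (state >= 0 && i > 0 && j > 0) {
    if (state == 0) {
      ai.push_back(i); bi.push_back(j);
      double need = M[at(i, j)];
      double s = (am[i - 1] & bm[j - 1]) ? match : mismatch;
      --i; --j;
      if (i == 0 || j == 0) break;
      if (M[at(i, j)] + s == need) state = 0;
      else if (X[at(i, j)] + s == need) state = 1;
      else state = 2;
    } else if (state == 1) {
      ai.push_back(i); bi.push_back(0);
      double need = X[at(i, j)];
      --i;
      if (i == 0) break;
      if (M[at(i, j)] + gap_open == need) state = 0;
      else if (Y[at(i, j)] + gap_open == need) state = 2;
      else state = 1;
    } else {
      ai.push_back(0); bi.push_back(j);
      double need = Y[at(i, j)];
      --j;
      if (j == 0) break;
      if (M[at(i, j)] + gap_open == need) state = 0;
      else if (X[at(i, j)] + gap_open == need) state = 1;
      else state = 2;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());

  return List::create(_["score"] = best,
                      _["a_idx"] = IntegerVector(ai.begin(), ai.end()),
                      _["b_idx"] = IntegerVector(bi.begin(), bi.end()),
                      _["start_i"] = i, _["start_j"] = j,
                      _["end_i"] = ei, _["end_j"] = ej);
}
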