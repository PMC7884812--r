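#include <Rcpp.h>
using namespace Rcpp;

// Smith-Waterman local alignment score under affine gaps (Gotoh).
//
// H(i,j) = max(0, H(i-1,j-1) + s(a_i, b_j), E(i,j), F(i,j))
// E(i,j) = max(H(i,j-1) - gap_open, E(i,j-1) - gap_extend)   gap in a
// F(i,j) = max(H(i-1,j) - gap_open, F(i-1,j) - gap_extend)   gap in b
//
// Gap cost convention: a gap of length L costs gap_open + (L-1)*gap_extend
// (the first gap residue costs gap_open alone).
//
// a_idx / b_idx are 0-based rows/columns into the scoring matrix. Ties on
// the maximal cell resolve to the smallest (i, j) in row-major order, i
// running over a.
// [[Rcpp::export(name = ".gotoh_score")]]
List gotoh_score(IntegerVector a_idx, IntegerVector b_idx,
                 IntegerMatrix score, int gap_open, int gap_extend) {
  const int m = a_idx.size(), n = b_idx.size();
  const int NEG = INT_MIN / 2;
  if (m == 0 || n == 0)
    return List::create(_["score"] = 0, _["query_end"] = NA_INTEGER,
                        _["subject_end"] = NA_INTEGER);
  std::vector<int> H(n + 1, 0), F(n + 1, NEG);
  int best = 0, best_i = NA_INTEGER, best_j = NA_INTEGER;
  for (int i = 1; i <= m; ++i) {
    int diag = 0;   // H(i-1, 0)
    int E = NEG;    // E(i, 0)
    const int ai = a_idx[i - 1];
    for (int j = 1; j <= n; ++j) {
      const int up = H[j];  // H(i-1, j)
      // H[j-1] already holds the current row's value H(i, j-1)
      E = std::max(H[j - 1] - gap_open, E - gap_extend);
      F[j] = std::max(up - gap_open, F[j] - gap_extend);
      int h = diag + score(ai, b_idx[j - 1]);
      if (E > h) h = E;
      if (F[j] > h) h = F[j];
      if (h < 0) h = 0;
      diag = up;
      H[j] = h;
      if (h > best) { best = h; best_i = i; best_j = j; }
    }
  }
  return List::create(_["score"] = best, _["query_end"] = best_i,
                      _["subject_end"] = best_j);
}
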