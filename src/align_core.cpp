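#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment of two column profiles under affine
// gap penalties. `score` is the (nA x nB) column-pair substitution score
// matrix already computed from the profiles and the residue scoring matrix.
// Gap cost for a run of length L is gap_open + gap_extend * L (both >= 0).
// Returns the aligned column index vectors (0 = gap) and the optimal score.
// Ties are broken in the fixed order match > gap-in-B (up) > gap-in-A (left),
// so the result is deterministic.
// [[Rcpp::export(name = ".affine_profile_align")]]
List affine_profile_align(NumericMatrix score, double gap_open,
                          double gap_extend) {
  const int n = score.nrow(), m = score.ncol();
  const double NEG = -1e18;
  // three-state DP: M diagonal, X gap in B (consumes A row), Y gap in A
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  IntegerMatrix tM(n + 1, m + 1), tX(n + 1, m + 1), tY(n + 1, m + 1);
  M(0, 0) = 0; X(0, 0) = NEG; Y(0, 0) = NEG;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG; Y(i, 0) = NEG;
    X(i, 0) = -(gap_open + gap_extend * i);
    tX(i, 0) = 1;
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG; X(0, j) = NEG;
    Y(0, j) = -(gap_open + gap_extend * j);
    tY(0, j) = 2;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // M: consume one column of each
      double s = score(i - 1, j - 1);
      double bm = M(i - 1, j - 1), bx = X(i - 1, j - 1), by = Y(i - 1, j - 1);
      int t = 0; double best = bm;
      if (bx > best) { best = bx; t = 1; }
      if (by > best) { best = by; t = 2; }
      M(i, j) = best + s; tM(i, j) = t;
      // X: gap in B, consume column i of A
      double xo = M(i - 1, j) - (gap_open + gap_extend);
      double xe = X(i - 1, j) - gap_extend;
      double xy = Y(i - 1, j) - (gap_open + gap_extend);
      t = 0; best = xo;
      if (xe > best) { best = xe; t = 1; }
      if (xy > best) { best = xy; t = 2; }
      X(i, j) = best; tX(i, j) = t;
      // Y: gap in A, consume column j of B
      double yo = M(i, j - 1) - (gap_open + gap_extend);
      double yx = X(i, j - 1) - (gap_open + gap_extend);
      double ye = Y(i, j - 1) - gap_extend;
      t = 0; best = yo;
      if (yx > best) { best = yx; t = 1; }
      if (ye > best) { best = ye; t = 2; }
      Y(i, j) = best; tY(i, j) = t;
    }
  }
  int state = 0;
  double best = M(n, m);
  if (X(n, m) > best) { best = X(n, m); state = 1; }
  if (Y(n, m) > best) { best = Y(n, m); state = 2; }
  // traceback
  std::vector<int> ai, bi;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      int prev = tM(i, j);
      ai.push_back(i); bi.push_back(j);
      --i; --j; state = prev;
    } else if (state == 1) {
      int prev = tX(i, j);
      ai.push_back(i); bi.push_back(0);
      --i; state = prev;
    } else {
      int prev = tY(i, j);
      ai.push_back(0); bi.push_back(j);
      --j; state = prev;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
  return List::create(_["a"] = wrap(ai), _["b"] = wrap(bi),
                      _["score"] = best);
}
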