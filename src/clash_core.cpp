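#include <Rcpp.h>
using namespace Rcpp;

// Pairs of atoms closer than scale * their pair threshold, skipping
// excluded (bonded-path) pairs. Returns a 3-column matrix: i, j (1-based),
// scaled threshold. Raw-pointer column access keeps the O(n^2) scan cheap.
// [[Rcpp::export(name = ".clash_pairs")]]
NumericMatrix clash_pairs(NumericMatrix xyz, NumericMatrix thr, double scale,
                          LogicalMatrix excl) {
  const int n = xyz.nrow();
  const double* X = REAL(xyz);
  const double* Y = X + n;
  const double* Z = X + 2 * n;
  const double* T = REAL(thr);
  const int* E = LOGICAL(excl);
  std::vector<double> out;
  for (int i = 0; i < n - 1; ++i) {
    const double xi = X[i], yi = Y[i], zi = Z[i];
    const double* Tcol = T + (size_t)i * n;
    const int* Ecol = E + (size_t)i * n;
    for (int j = i + 1; j < n; ++j) {
      if (Ecol[j]) continue;
      const double t = scale * Tcol[j];
      const double dx = X[j] - xi, dy = Y[j] - yi, dz = Z[j] - zi;
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < t * t) {
        out.push_back(i + 1);
        out.push_back(j + 1);
        out.push_back(t);
      }
    }
  }
  const int m = out.size() / 3;
  NumericMatrix res(m, 3);
  for (int k = 0; k < m; ++k) {
    res(k, 0) = out[3 * k];
    res(k, 1) = out[3 * k + 1];
    res(k, 2) = out[3 * k + 2];
  }
  return res;
}
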