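#include <Rcpp.h>
using namespace Rcpp;

static inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}

// Cyclic coordinate descent closure. `xyz` holds the anchor N/CA/C in its
// first three rows (fixed) and the rebuilt chain after them; the last three
// rows are the rebuilt downstream-anchor backbone that must land on
// `target` (3 x 3). `handles` has one row per torsion: columns are the
// 1-based rows of the axis atoms a, b and the first moving row. Iterates
// until the target RMSD drops below `tol` or `max_iter` passes.
// [[Rcpp::export(name = ".ccd_close")]]
List ccd_close(NumericMatrix xyz_in, IntegerMatrix handles,
               NumericMatrix target, double tol, int max_iter) {
  NumericMatrix xyz = clone(xyz_in);
  const int n = xyz.nrow();
  const int nh = handles.nrow();
  const int t0 = n - 3;

  auto gap = [&]() {
    double s = 0;
    for (int k = 0; k < 3; ++k) {
      for (int c = 0; c < 3; ++c) {
        double d = xyz(t0 + k, c) - target(k, c);
        s += d * d;
      }
    }
    return std::sqrt(s / 3.0);
  };

  double g = gap();
  int iter = 0;
  while (g > tol && iter < max_iter) {
    for (int h = 0; h < nh; ++h) {
      const int ia = handles(h, 0) - 1, ib = handles(h, 1) - 1;
      const int from = handles(h, 2) - 1;
      double a[3], u[3];
      double un = 0;
      for (int c = 0; c < 3; ++c) {
        a[c] = xyz(ia, c);
        u[c] = xyz(ib, c) - a[c];
        un += u[c] * u[c];
      }
      un = std::sqrt(un);
      if (un < 1e-9) continue;
      for (int c = 0; c < 3; ++c) u[c] /= un;
      double num = 0, den = 0;
      for (int k = 0; k < 3; ++k) {
        double M[3], F[3], r[3], f[3], cx[3];
        double proj = 0;
        for (int c = 0; c < 3; ++c) {
          M[c] = xyz(t0 + k, c) - a[c];
          F[c] = target(k, c) - a[c];
          proj += M[c] * u[c];
        }
        double projF = 0;
        for (int c = 0; c < 3; ++c) projF += F[c] * u[c];
        for (int c = 0; c < 3; ++c) {
          r[c] = M[c] - proj * u[c];
          f[c] = F[c] - projF * u[c];
        }
        cross3(u, r, cx);
        for (int c = 0; c < 3; ++c) {
          den += f[c] * r[c];
          num += f[c] * cx[c];
        }
      }
      double theta = std::atan2(num, den);
      if (std::fabs(theta) < 1e-12) continue;
      double ct = std::cos(theta), st = std::sin(theta);
      for (int i = from; i < n; ++i) {
        double p[3], rot[3], cx[3];
        double proj = 0;
        for (int c = 0; c < 3; ++c) {
          p[c] = xyz(i, c) - a[c];
          proj += p[c] * u[c];
        }
        cross3(u, p, cx);
        for (int c = 0; c < 3; ++c) {
          rot[c] = p[c] * ct + cx[c] * st + u[c] * proj * (1 - ct);
          xyz(i, c) = rot[c] + a[c];
        }
      }
    }
    g = gap();
    ++iter;
  }
  return List::create(_["xyz"] = xyz, _["gap"] = g, _["iter"] = iter);
}
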