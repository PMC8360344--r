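#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Magnetic field of a set of straight current segments at arbitrary points,
// using the Hanson-Hirshman closed form for a finite filament:
//   B = (mu0 I / 4pi) * (r1 x r2) (|r1| + |r2|) / (|r1||r2|(|r1||r2| + r1.r2))
// which is singular only on the filament itself.  Points closer to any
// segment than `min_dist` are flagged by returning NaN for that point so the
// R wrapper can raise an informative error.
//
// seg_a, seg_b : n_seg x 3 segment start/end points (m)
// pts          : n_pts x 3 evaluation points (m)
// current      : filament current (A)
// min_dist     : singularity guard distance (m)
// [[Rcpp::export]]
NumericMatrix bs_field_cpp(NumericMatrix seg_a, NumericMatrix seg_b,
                           NumericMatrix pts, double current,
                           double min_dist) {
  const double mu0_4pi = 1e-7;
  const int ns = seg_a.nrow(), np = pts.nrow();
  const double md2 = min_dist * min_dist;
  NumericMatrix B(np, 3);

  std::vector<double> ax(ns), ay(ns), az(ns), lx(ns), ly(ns), lz(ns), ll(ns);
  for (int s = 0; s < ns; ++s) {
    ax[s] = seg_a(s, 0); ay[s] = seg_a(s, 1); az[s] = seg_a(s, 2);
    lx[s] = seg_b(s, 0) - ax[s];
    ly[s] = seg_b(s, 1) - ay[s];
    lz[s] = seg_b(s, 2) - az[s];
    ll[s] = lx[s] * lx[s] + ly[s] * ly[s] + lz[s] * lz[s];
  }

  for (int i = 0; i < np; ++i) {
    const double px = pts(i, 0), py = pts(i, 1), pz = pts(i, 2);
    double bx = 0.0, by = 0.0, bz = 0.0;
    bool bad = false;
    for (int s = 0; s < ns; ++s) {
      if (ll[s] == 0.0) continue;  // degenerate (zero-length) segment
      const double r1x = px - ax[s], r1y = py - ay[s], r1z = pz - az[s];
      const double r2x = r1x - lx[s], r2y = r1y - ly[s], r2z = r1z - lz[s];
      // distance to the segment (clamped projection)
      double t = (r1x * lx[s] + r1y * ly[s] + r1z * lz[s]) / ll[s];
      if (t < 0.0) t = 0.0; else if (t > 1.0) t = 1.0;
      const double dx = r1x - t * lx[s], dy = r1y - t * ly[s],
                   dz = r1z - t * lz[s];
      if (dx * dx + dy * dy + dz * dz < md2) { bad = true; break; }
      const double n1 = std::sqrt(r1x * r1x + r1y * r1y + r1z * r1z);
      const double n2 = std::sqrt(r2x * r2x + r2y * r2y + r2z * r2z);
      const double dot = r1x * r2x + r1y * r2y + r1z * r2z;
      const double k = (n1 + n2) / (n1 * n2 * (n1 * n2 + dot));
      bx += (r1y * r2z - r1z * r2y) * k;
      by += (r1z * r2x - r1x * r2z) * k;
      bz += (r1x * r2y - r1y * r2x) * k;
    }
    if (bad) {
      B(i, 0) = NA_REAL; B(i, 1) = NA_REAL; B(i, 2) = NA_REAL;
    } else {
      const double f = mu0_4pi * current;
      B(i, 0) = f * bx; B(i, 1) = f * by; B(i, 2) = f * bz;
    }
  }
  return B;
}
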