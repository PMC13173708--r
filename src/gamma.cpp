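// Global-normalisation gamma index with discrete distance search.
//
// For each reference voxel above the low-dose threshold, gamma is minimised
// over displacement candidates on a 3x refined grid (steps spacing/3 per
// axis) within a search radius of 3 * dta. The evaluated dose is sampled by
// trilinear interpolation at the displaced physical position. Candidates are
// visited in order of increasing |r| so the distance term alone allows early
// termination.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
#include <algorithm>
using namespace Rcpp;

struct Offset { double ry, rx, rz, dist2; };

static double trilin(const double* a, int d1, int d2, int d3,
                     double i, double j, double k) {
  // fractional 0-based voxel coordinates, clamped to the volume
  i = std::min(std::max(i, 0.0), d1 - 1.0);
  j = std::min(std::max(j, 0.0), d2 - 1.0);
  k = std::min(std::max(k, 0.0), d3 - 1.0);
  int i0 = std::min((int)i, d1 - 2), j0 = std::min((int)j, d2 - 2),
      k0 = std::min((int)k, d3 - 2);
  if (d1 == 1) i0 = 0; if (d2 == 1) j0 = 0; if (d3 == 1) k0 = 0;
  double fi = i - i0, fj = j - j0, fk = k - k0;
  double out = 0.0;
  for (int ck = 0; ck <= (d3 > 1 ? 1 : 0); ++ck)
    for (int cj = 0; cj <= (d2 > 1 ? 1 : 0); ++cj)
      for (int ci = 0; ci <= (d1 > 1 ? 1 : 0); ++ci) {
        double w = (ci ? fi : 1 - fi) * (cj ? fj : 1 - fj) * (ck ? fk : 1 - fk);
        out += w * a[(i0 + ci) + d1 * ((j0 + cj) + d2 * (k0 + ck))];
      }
  return out;
}

// Returns per-voxel gamma for evaluable voxels (NA elsewhere).
// dd_abs: dose-difference criterion in Gy (already % of ref max);
// thresh: absolute low-dose cutoff in Gy.
// [[Rcpp::export]]
NumericVector cpp_gamma(NumericVector ref, NumericVector eval,
                        IntegerVector dims, NumericVector spacing,
                        double dd_abs, double dta, double thresh) {
  int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  double dy = spacing[0], dx = spacing[1], dz = spacing[2];
  double radius = 3.0 * dta;
  // displacement candidates on the refined grid
  std::vector<Offset> offs;
  int ny = (int)std::floor(radius / (dy / 3.0));
  int nx = (int)std::floor(radius / (dx / 3.0));
  int nz = (int)std::floor(radius / (dz / 3.0));
  for (int a = -ny; a <= ny; ++a)
    for (int b = -nx; b <= nx; ++b)
      for (int c = -nz; c <= nz; ++c) {
        double ry = a * dy / 3.0, rx = b * dx / 3.0, rz = c * dz / 3.0;
        double r2 = ry * ry + rx * rx + rz * rz;
        if (r2 <= radius * radius) offs.push_back({ry, rx, rz, r2});
      }
  std::sort(offs.begin(), offs.end(),
            [](const Offset& u, const Offset& v) { return u.dist2 < v.dist2; });
  const double* ev = eval.begin();
  NumericVector out(ref.size(), NA_REAL);
  double dta2 = dta * dta, dd2 = dd_abs * dd_abs;
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        int v = i + d1 * (j + d2 * k);
        double rd = ref[v];
        if (rd < thresh) continue;
        double best = R_PosInf;
        for (const Offset& o : offs) {
          double dterm = o.dist2 / dta2;
          if (dterm >= best) break; // sorted: no later candidate can win
          double ev_d = trilin(ev, d1, d2, d3,
                               i + o.ry / dy, j + o.rx / dx, k + o.rz / dz);
          double diff = ev_d - rd;
          double g2 = dterm + diff * diff / dd2;
          if (g2 < best) best = g2;
        }
        out[v] = std::sqrt(best);
      }
  return out;
}
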