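// Parallel-ray depth maps for the surrogate dose engine.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Radiological depth (mm of body material traversed before each pixel) for a
// parallel beam at `angle_rad` in the axial plane. The beam direction is
// d = (cos a, sin a) in physical (row, col) = (y, x) coordinates; depth at a
// pixel is the body path length integrated upstream (along -d) from the pixel
// centre to the slice edge, sampled with step `step_mm` at nearest-pixel
// lookups. Deterministic.
// [[Rcpp::export]]
NumericMatrix cpp_depth_slice(IntegerMatrix body, double dy, double dx,
                              double angle_rad, double step_mm) {
  int nr = body.nrow(), nc = body.ncol();
  NumericMatrix out(nr, nc);
  double cy = std::cos(angle_rad), cx = std::sin(angle_rad); // (row, col) dir
  double Ly = nr * dy, Lx = nc * dx;
  double Lmax = std::sqrt(Ly * Ly + Lx * Lx);
  int nstep = (int)std::ceil(Lmax / step_mm);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double y0 = (i + 0.5) * dy, x0 = (j + 0.5) * dx;
      double acc = 0.0;
      for (int s = 1; s <= nstep; ++s) {
        double y = y0 - cy * step_mm * s;
        double x = x0 - cx * step_mm * s;
        if (y < 0 || x < 0 || y >= Ly || x >= Lx) break;
        int ii = (int)(y / dy), jj = (int)(x / dx);
        if (body(ii, jj)) acc += step_mm;
      }
      out(i, j) = acc;
    }
  }
  return out;
}
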