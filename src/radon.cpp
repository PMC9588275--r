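#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Bilinear sample with zero outside the grid (air contributes nothing).
static inline double bilinear(const NumericMatrix &img, double x, double y) {
  int n = img.nrow(), m = img.ncol();
  if (x < 0.0 || y < 0.0 || x > n - 1.0 || y > m - 1.0) return 0.0;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
  int x1 = x0 + 1 < n ? x0 + 1 : x0;
  int y1 = y0 + 1 < m ? y0 + 1 : y0;
  double fx = x - x0, fy = y - y0;
  return img(x0, y0) * (1 - fx) * (1 - fy) + img(x1, y0) * fx * (1 - fy) +
         img(x0, y1) * (1 - fx) * fy + img(x1, y1) * fx * fy;
}

// Parallel-beam Radon transform: line integrals of `mu` (values per pixel
// step) over rays t = x cos(a) + y sin(a), unit pixel integration step.
// Each detector bin integrates `n_sub` parallel sub-rays across its width
// (finite detector aperture); n_sub = 1 recovers ideal zero-width rays.
// [[Rcpp::export(rng = false)]]
NumericMatrix radon_forward(NumericMatrix mu, NumericVector angles_rad,
                            int n_sub = 1) {
  int n = mu.nrow();
  int na = angles_rad.size();
  NumericMatrix out(na, n);
  double c = (n - 1) / 2.0;
  int smax = (int)std::ceil(n * 0.71) + 1;
  for (int ia = 0; ia < na; ia++) {
    double ca = std::cos(angles_rad[ia]), sa = std::sin(angles_rad[ia]);
    for (int j = 0; j < n; j++) {
      double acc = 0.0;
      for (int sub = 0; sub < n_sub; sub++) {
        double t = j - c + (n_sub > 1 ? (sub + 0.5) / n_sub - 0.5 : 0.0);
        for (int s = -smax; s <= smax; s++) {
          double x = c + t * ca - s * sa;
          double y = c + t * sa + s * ca;
          acc += bilinear(mu, x, y);
        }
      }
      out(ia, j) = acc / n_sub;
    }
  }
  return out;
}

// Back projection of filtered projections (rows = angles), linear
// interpolation across detector bins. Caller applies the pi/n_angles weight.
// [[Rcpp::export(rng = false)]]
NumericMatrix radon_backproject(NumericMatrix filt, NumericVector angles_rad,
                                int size) {
  int na = angles_rad.size();
  int nd = filt.ncol();
  NumericMatrix out(size, size);
  double c = (size - 1) / 2.0;
  double cd = (nd - 1) / 2.0;
  for (int ia = 0; ia < na; ia++) {
    double ca = std::cos(angles_rad[ia]), sa = std::sin(angles_rad[ia]);
    for (int iy = 0; iy < size; iy++) {
      double yt = (iy - c) * sa;
      for (int ix = 0; ix < size; ix++) {
        double t = (ix - c) * ca + yt + cd;
        if (t < 0.0 || t > nd - 1.0) continue;
        int t0 = (int)std::floor(t);
        int t1 = t0 + 1 < nd ? t0 + 1 : t0;
        double ft = t - t0;
        out(ix, iy) += filt(ia, t0) * (1 - ft) + filt(ia, t1) * ft;
      }
    }
  }
  return out;
}
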