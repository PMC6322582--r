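#include <Rcpp.h>
using namespace Rcpp;

// Bilinear sample of img at fractional (row, col), zero outside the grid.
static inline double bilin(const NumericMatrix &img, double r, double c) {
  const int nr = img.nrow(), nc = img.ncol();
  if (r < 0 || c < 0 || r > nr - 1 || c > nc - 1) return 0.0;
  int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
  int r1 = std::min(r0 + 1, nr - 1), c1 = std::min(c0 + 1, nc - 1);
  double fr = r - r0, fc = c - c0;
  return (1 - fr) * ((1 - fc) * img(r0, c0) + fc * img(r0, c1)) +
         fr * ((1 - fc) * img(r1, c0) + fc * img(r1, c1));
}

// Discrete Radon transform of a square image: one detector row per angle.
// Detector bin s and integration variable t both step one pixel; the ray for
// angle theta passes through (x, y) = center + R(theta) * (s - c, t - c).
// [[Rcpp::export]]
NumericMatrix cpp_radon(NumericMatrix img, NumericVector angles_deg) {
  const int n = img.nrow();
  if (img.ncol() != n) stop("image must be square");
  const int na = angles_deg.size();
  NumericMatrix out(na, n);
  const double c0 = n / 2; // floor-center convention
  for (int a = 0; a < na; ++a) {
    const double th = angles_deg[a] * M_PI / 180.0;
    const double ct = std::cos(th), st = std::sin(th);
    for (int s = 0; s < n; ++s) {
      const double ds = s - c0;
      double acc = 0.0;
      for (int t = 0; t < n; ++t) {
        const double dt = t - c0;
        const double x = c0 + ds * ct + dt * st; // column
        const double y = c0 - ds * st + dt * ct; // row
        acc += bilin(img, y, x);
      }
      out(a, s) = acc;
    }
  }
  return out;
}

// Back-projection of (already filtered) projections onto an n x n grid with
// linear interpolation along the detector. No angular normalization here.
// [[Rcpp::export]]
NumericMatrix cpp_backproject(NumericMatrix sino, NumericVector angles_deg,
                              int output_size) {
  const int na = sino.nrow(), nd = sino.ncol();
  if (na != angles_deg.size()) stop("row count must equal angle count");
  NumericMatrix out(output_size, output_size);
  const double c0 = output_size / 2; // floor-center convention
  const double cd = nd / 2;
  for (int a = 0; a < na; ++a) {
    const double th = angles_deg[a] * M_PI / 180.0;
    const double ct = std::cos(th), st = std::sin(th);
    for (int y = 0; y < output_size; ++y) {
      const double dy = y - c0;
      for (int x = 0; x < output_size; ++x) {
        const double dx = x - c0;
        const double s = dx * ct - dy * st + cd;
        if (s < 0 || s > nd - 1) continue;
        int s0 = (int)std::floor(s);
        int s1 = std::min(s0 + 1, nd - 1);
        double fs = s - s0;
        out(y, x) += (1 - fs) * sino(a, s0) + fs * sino(a, s1);
      }
    }
  }
  return out;
}
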