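#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Reflect index into [0, n-1] (mirror without repeating the edge sample
// unless n == 1). Assumes |i| stays within a few multiples of n.
static inline int reflect(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// One direct bilateral pass. Intensities are on the 0..255 scale and
// sigma_r is already in intensity levels. The spatial kernel is truncated
// at `truncate` spatial sigmas; borders are reflect-padded.
// [[Rcpp::export]]
NumericMatrix cpp_bilateral(NumericMatrix img, double sigma_s, double sigma_r,
                            double truncate = 3.0) {
  const int nr = img.nrow(), nc = img.ncol();
  const int rad = std::max(1, (int)std::ceil(truncate * sigma_s));
  const double is2 = 1.0 / (2.0 * sigma_s * sigma_s);
  const double ir2 = 1.0 / (2.0 * sigma_r * sigma_r);

  // spatial weights (separable lookup for the radial profile)
  std::vector<double> sw(2 * rad + 1);
  for (int d = -rad; d <= rad; ++d) sw[d + rad] = std::exp(-(double)d * d * is2);

  // range weights: lookup table over the squared-difference exponent
  const int nlut = 4096;
  const double xmax = 20.0; // exp(-20) ~ 2e-9, below any useful weight
  std::vector<double> lut(nlut + 1);
  for (int t = 0; t <= nlut; ++t) lut[t] = std::exp(-xmax * t / nlut);
  const double lscale = nlut / xmax;

  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      const double v0 = img(i, j);
      double num = 0.0, den = 0.0;
      for (int dj = -rad; dj <= rad; ++dj) {
        const int jj = reflect(j + dj, nc);
        const double wj = sw[dj + rad];
        if (wj < 1e-12) continue;
        for (int di = -rad; di <= rad; ++di) {
          const int ii = reflect(i + di, nr);
          const double ws = wj * sw[di + rad];
          if (ws < 1e-12) continue;
          const double v = img(ii, jj);
          const double dv = v - v0;
          const double x = dv * dv * ir2;
          if (x >= xmax) continue;
          const double w = ws * lut[(int)(x * lscale)];
          num += w * v;
          den += w;
        }
      }
      out(i, j) = num / den;
    }
  }
  return out;
}

// Fast bilateral approximation on the bilateral grid: the image is
// downsampled into a coarse (x, y, intensity) grid at sampling rates
// (sigma_s, sigma_s, sigma_r), the grid is convolved with a unit-sigma
// Gaussian along each axis, and the result is read back by trilinear
// interpolation ("slicing"). Homogeneous (value, weight) accumulation.
// [[Rcpp::export]]
NumericMatrix cpp_bilateral_grid(NumericMatrix img, double sigma_s, double sigma_r) {
  const int nr = img.nrow(), nc = img.ncol();
  double vmin = img(0, 0), vmax = img(0, 0);
  for (int k = 0; k < nr * nc; ++k) {
    if (img[k] < vmin) vmin = img[k];
    if (img[k] > vmax) vmax = img[k];
  }
  if (vmax - vmin < 1e-12) return clone(img);

  const int pad = 2;
  const int gx = (int)((nr - 1) / sigma_s) + 1 + 2 * pad;
  const int gy = (int)((nc - 1) / sigma_s) + 1 + 2 * pad;
  const int gz = (int)((vmax - vmin) / sigma_r) + 1 + 2 * pad;
  const size_t n = (size_t)gx * gy * gz;
  std::vector<double> wv(n, 0.0), w(n, 0.0);
  auto at = [&](int x, int y, int z) -> size_t {
    return (size_t)x + (size_t)gx * ((size_t)y + (size_t)gy * z);
  };

  // downsample (nearest-grid-point splatting)
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      const double v = img(i, j);
      const int x = (int)std::lround(i / sigma_s) + pad;
      const int y = (int)std::lround(j / sigma_s) + pad;
      const int z = (int)std::lround((v - vmin) / sigma_r) + pad;
      wv[at(x, y, z)] += v;
      w[at(x, y, z)] += 1.0;
    }

  // 5-tap unit-sigma Gaussian along each axis
  const double k0 = 1.0, k1 = std::exp(-0.5), k2 = std::exp(-2.0);
  const double ks = k0 + 2 * k1 + 2 * k2;
  const double kk[5] = {k2 / ks, k1 / ks, k0 / ks, k1 / ks, k2 / ks};
  std::vector<double> tmp(n);
  const int dims[3] = {gx, gy, gz};
  const size_t strides[3] = {1, (size_t)gx, (size_t)gx * gy};
  for (int axis = 0; axis < 3; ++axis) {
    for (std::vector<double>* buf : {&wv, &w}) {
      std::vector<double>& b = *buf;
      for (int z = 0; z < gz; ++z)
        for (int y = 0; y < gy; ++y)
          for (int x = 0; x < gx; ++x) {
            const int c[3] = {x, y, z};
            const size_t idx = at(x, y, z);
            double acc = 0.0;
            for (int t = -2; t <= 2; ++t) {
              int p = c[axis] + t;
              if (p < 0) p = 0;
              if (p >= dims[axis]) p = dims[axis] - 1;
              acc += kk[t + 2] * b[idx + ((size_t)p - c[axis]) * strides[axis]];
            }
            tmp[idx] = acc;
          }
      b.swap(tmp);
    }
  }

  // slice with trilinear interpolation
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      const double v = img(i, j);
      const double fx = i / sigma_s + pad;
      const double fy = j / sigma_s + pad;
      const double fz = (v - vmin) / sigma_r + pad;
      const int x0 = (int)fx, y0 = (int)fy, z0 = (int)fz;
      const double ax = fx - x0, ay = fy - y0, az = fz - z0;
      double sw_ = 0.0, swv = 0.0;
      for (int dz = 0; dz <= 1; ++dz)
        for (int dy = 0; dy <= 1; ++dy)
          for (int dx = 0; dx <= 1; ++dx) {
            const int x = std::min(x0 + dx, gx - 1);
            const int y = std::min(y0 + dy, gy - 1);
            const int z = std::min(z0 + dz, gz - 1);
            const double wt = (dx ? ax : 1 - ax) * (dy ? ay : 1 - ay) * (dz ? az : 1 - az);
            swv += wt * wv[at(x, y, z)];
            sw_ += wt * w[at(x, y, z)];
          }
      out(i, j) = sw_ > 1e-12 ? swv / sw_ : v;
      if (out(i, j) < vmin) out(i, j) = vmin;
      if (out(i, j) > vmax) out(i, j) = vmax;
    }
  return out;
}
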