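#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Separable Gaussian smoothing with an amplitude-one kernel (value 1 at
// the peak), so a smoothed accumulator value approximates the proximity-
// weighted number of votes near that point rather than a local average.
static void gauss_blur_plane(double* p, int nr, int nc, double sigma) {
  const int rad = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * rad + 1);
  for (int d = -rad; d <= rad; ++d)
    k[d + rad] = std::exp(-0.5 * d * d / (sigma * sigma));
  std::vector<double> tmp((size_t)nr * nc);
  // along i (within each column, contiguous)
  for (int j = 0; j < nc; ++j) {
    const double* src = p + (size_t)nr * j;
    double* dst = tmp.data() + (size_t)nr * j;
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int d = -rad; d <= rad; ++d) {
        int ii = i + d;
        if (ii < 0) ii = 0;
        if (ii >= nr) ii = nr - 1;
        acc += k[d + rad] * src[ii];
      }
      dst[i] = acc;
    }
  }
  // along j (column-wise weighted accumulation, contiguous inner loops)
  std::fill(p, p + (size_t)nr * nc, 0.0);
  for (int j = 0; j < nc; ++j) {
    double* dst = p + (size_t)nr * j;
    for (int d = -rad; d <= rad; ++d) {
      int jj = j + d;
      if (jj < 0) jj = 0;
      if (jj >= nc) jj = nc - 1;
      const double w = k[d + rad];
      const double* src = tmp.data() + (size_t)nr * jj;
      for (int i = 0; i < nr; ++i) dst[i] += w * src[i];
    }
  }
}

// Circle Hough accumulator with normal-directed (compact) voting. Every
// boundary pixel estimates its inward normal from the local mask content
// and casts, for each candidate radius r, one vote at the point r pixels
// along that normal — the center a circle of radius r through this pixel
// would have. Each (x, y) plane is then smoothed with a Gaussian of std
// acc_sigma and, when normalize is true, divided by the candidate
// circumference so the score approximates the fraction of the circle's
// boundary that is present (full circle -> about 1, independent of size).
// [[Rcpp::export]]
NumericVector cpp_hough_accumulate(LogicalMatrix mask,
                                   IntegerVector bi, IntegerVector bj,
                                   IntegerVector radii,
                                   double acc_sigma, bool normalize,
                                   int normal_window = 5) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const int nrad = radii.size();
  const size_t plane = (size_t)nr * nc;
  NumericVector acc(plane * nrad);

  // inward normal per boundary pixel: direction toward the local mask mass
  const int w = normal_window;
  std::vector<double> ni(bi.size()), nj(bi.size());
  for (int b = 0; b < bi.size(); ++b) {
    const int i0 = bi[b], j0 = bj[b];
    double si = 0.0, sj = 0.0;
    for (int dj = -w; dj <= w; ++dj) {
      const int jj = j0 + dj;
      if (jj < 0 || jj >= nc) continue;
      for (int di = -w; di <= w; ++di) {
        const int ii = i0 + di;
        if (ii < 0 || ii >= nr || di * di + dj * dj > w * w) continue;
        if (mask(ii, jj)) { si += di; sj += dj; }
      }
    }
    const double len = std::sqrt(si * si + sj * sj);
    if (len < 1e-9) { ni[b] = NA_REAL; nj[b] = NA_REAL; }
    else { ni[b] = si / len; nj[b] = sj / len; }
  }

  for (int k = 0; k < nrad; ++k) {
    double* p = REAL(acc) + plane * k;
    const double r = radii[k];
    for (int b = 0; b < bi.size(); ++b) {
      if (ISNAN(ni[b])) continue;
      const int i = (int)std::lround(bi[b] + r * ni[b]);
      const int j = (int)std::lround(bj[b] + r * nj[b]);
      if (i >= 0 && j >= 0 && i < nr && j < nc) p[(size_t)i + (size_t)nr * j] += 1.0;
    }
    if (acc_sigma > 0) gauss_blur_plane(p, nr, nc, acc_sigma);
    if (normalize) {
      const double circ = 2.0 * M_PI * r;
      for (size_t t = 0; t < plane; ++t) p[t] /= circ;
    }
  }
  acc.attr("dim") = IntegerVector::create(nr, nc, nrad);
  return acc;
}

// Iterative peak extraction with relevance-threshold stopping. The global
// maximum of the (completeness-normalized) accumulator gives the next
// center and the stopping score; the radius is then re-estimated as the
// best-supported plane of the raw vote column at that center (the
// circumference normalization would otherwise bias radii low, since
// nearby planes receive ring-shaped vote residues). After each extraction
// a cylinder of the estimated radius (at least suppress_min) around the
// peak is zeroed across all radius planes so the same nucleus cannot be
// re-detected. Extraction stops when the current maximum is no longer
// strictly above relevance times the first maximum. Returns a matrix with
// columns (i, j, radius, score), 0-based pixel indices.
// [[Rcpp::export]]
NumericMatrix cpp_hough_detect(NumericVector acc, IntegerVector radii,
                               double relevance, int suppress_min,
                               int max_circles, bool normalized = true) {
  IntegerVector dim = acc.attr("dim");
  const int nr = dim[0], nc = dim[1], nrad = dim[2];
  const size_t plane = (size_t)nr * nc;
  std::vector<double> a(acc.begin(), acc.end());
  std::vector<double> out;
  double first = -1.0;
  int found = 0;
  while (found < max_circles) {
    size_t best = 0;
    double m = -1.0;
    for (size_t t = 0; t < a.size(); ++t)
      if (a[t] > m) { m = a[t]; best = t; }
    if (m <= 0) break;
    if (first < 0) first = m;
    else if (m <= relevance * first) break;
    const size_t rem = best % plane;
    const int j = (int)(rem / nr);
    const int i = (int)(rem % nr);
    // radius: best-supported plane of the raw vote column at this center
    int kbest = (int)(best / plane);
    double vbest = -1.0;
    for (int k = 0; k < nrad; ++k) {
      double v = a[rem + plane * k];
      if (normalized) v *= radii[k]; // undo the 1/circumference factor
      if (v > vbest) { vbest = v; kbest = k; }
    }
    out.push_back(i); out.push_back(j);
    out.push_back(radii[kbest]); out.push_back(m);
    ++found;
    // suppress a cylinder across all radius planes
    const int sr = std::max(suppress_min, (int)radii[kbest]);
    const int r2 = sr * sr;
    for (int dj = -sr; dj <= sr; ++dj) {
      const int jj = j + dj;
      if (jj < 0 || jj >= nc) continue;
      for (int di = -sr; di <= sr; ++di) {
        const int ii = i + di;
        if (ii < 0 || ii >= nr || di * di + dj * dj > r2) continue;
        for (int kk = 0; kk < nrad; ++kk)
          a[(size_t)ii + (size_t)nr * jj + plane * kk] = 0.0;
      }
    }
  }
  NumericMatrix res(found, 4);
  for (int t = 0; t < found; ++t)
    for (int c = 0; c < 4; ++c) res(t, c) = out[4 * t + c];
  colnames(res) = CharacterVector::create("i", "j", "r", "score");
  return res;
}
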