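#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <functional>
using namespace Rcpp;

// Two-pass 8-connected labeling with union-find. Labels are assigned in
// raster order (row-major over the matrix), 1-based; 0 is background.
// [[Rcpp::export]]
IntegerMatrix cpp_label8(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent(1, 0);
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  };

  int next = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j)) continue;
      int best = 0;
      // previously visited 8-neighbours in column-major scan order
      const int di[4] = {-1, -1, 0, 1};
      const int dj[4] = {0, -1, -1, -1};
      for (int k = 0; k < 4; ++k) {
        const int ii = i + di[k], jj = j + dj[k];
        if (ii < 0 || jj < 0 || ii >= nr || jj >= nc) continue;
        const int l = lab(ii, jj);
        if (l > 0) {
          if (best == 0) best = l;
          else unite(best, l);
        }
      }
      if (best == 0) {
        best = ++next;
        parent.push_back(best);
      }
      lab(i, j) = best;
    }

  // flatten and renumber 1..n in order of first appearance
  std::vector<int> newid(next + 1, 0);
  int nlab = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (lab(i, j) == 0) continue;
      const int r = find(lab(i, j));
      if (newid[r] == 0) newid[r] = ++nlab;
      lab(i, j) = newid[r];
    }
  return lab;
}

// Moore-neighbour boundary trace of one labeled component, summing step
// lengths (1 for axis moves, sqrt(2) for diagonal moves). An isolated
// pixel is assigned perimeter 4 by convention; width-1 structures are
// traced out and back so both sides count.
static double trace_one(const IntegerMatrix& lab, int label,
                        int si, int sj) {
  const int nr = lab.nrow(), nc = lab.ncol();
  auto fg = [&](int i, int j) {
    return i >= 0 && j >= 0 && i < nr && j < nc && lab(i, j) == label;
  };
  // clockwise neighbour order (image rows grow downward): W NW N NE E SE S SW
  const int di[8] = {0, -1, -1, -1, 0, 1, 1, 1};
  const int dj[8] = {-1, -1, 0, 1, 1, 1, 0, -1};

  // start: leftmost column, topmost row; backtrack points W (outside)
  int ci = si, cj = sj;
  int bdir = 0; // direction from current pixel toward the backtrack cell
  double per = 0.0;
  const long maxsteps = 4L * nr * nc + 8;
  long steps = 0;
  int first_i = si, first_j = sj, first_move = -1;
  while (true) {
    int found = -1;
    for (int k = 1; k <= 8; ++k) {
      const int d = (bdir + k) % 8;
      if (fg(ci + di[d], cj + dj[d])) { found = d; break; }
    }
    if (found < 0) return 4.0; // isolated pixel
    if (first_move < 0) first_move = found;
    else if (ci == first_i && cj == first_j && found == first_move) break;
    per += (di[found] != 0 && dj[found] != 0) ? std::sqrt(2.0) : 1.0;
    // backtrack for the next pixel: the cell examined just before `found`
    const int prev = (found + 7) % 8;
    const int bi = ci + di[prev], bj = cj + dj[prev];
    ci += di[found]; cj += dj[found];
    // direction from the new current pixel toward (bi, bj)
    bdir = 0;
    for (int d = 0; d < 8; ++d)
      if (ci + di[d] == bi && cj + dj[d] == bj) { bdir = d; break; }
    if (++steps > maxsteps) break;
  }
  return per;
}

// Perimeter of every labeled component (outer boundary trace).
// [[Rcpp::export]]
NumericVector cpp_perimeters(IntegerMatrix lab, int nlabels) {
  const int nr = lab.nrow(), nc = lab.ncol();
  std::vector<int> si(nlabels + 1, -1), sj(nlabels + 1, -1);
  // leftmost-topmost pixel per label (column-major scan finds it first)
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      const int l = lab(i, j);
      if (l > 0 && si[l] < 0) { si[l] = i; sj[l] = j; }
    }
  NumericVector per(nlabels);
  for (int l = 1; l <= nlabels; ++l)
    per[l - 1] = si[l] >= 0 ? trace_one(lab, l, si[l], sj[l]) : NA_REAL;
  return per;
}
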