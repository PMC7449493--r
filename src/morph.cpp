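// 3-D binary / grayscale morphology and connectivity primitives.
// All volumes are passed as flat vectors with explicit dims (d1, d2, d3),
// column-major (d1 fastest), matching R array storage. Structuring elements
// are integer offset matrices (n x 3) in the same index order; a flat
// (first-axis offset = 0) element makes every operation slice-wise.

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

static inline int lin(int i, int j, int k, int d1, int d2) {
  return i + d1 * (j + d2 * k);
}

static void neighbor_offsets(int connectivity, std::vector<std::array<int,3>> &off) {
  off.clear();
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        int manh = std::abs(a) + std::abs(b) + std::abs(c);
        if (connectivity == 6 && manh != 1) continue;
        off.push_back({a, b, c});
      }
}

// [[Rcpp::export]]
IntegerVector cpp_label(LogicalVector mask, int d1, int d2, int d3, int connectivity) {
  const int n = d1 * d2 * d3;
  IntegerVector lab(n, 0);
  std::vector<std::array<int,3>> off;
  neighbor_offsets(connectivity, off);
  int next = 0;
  std::vector<int> stack;
  for (int s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      int i = cur % d1, rem = cur / d1, j = rem % d2, k = rem / d2;
      for (size_t t = 0; t < off.size(); ++t) {
        int ii = i + off[t][0], jj = j + off[t][1], kk = k + off[t][2];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= d1 || jj >= d2 || kk >= d3) continue;
        int q = lin(ii, jj, kk, d1, d2);
        if (mask[q] && lab[q] == 0) { lab[q] = next; stack.push_back(q); }
      }
    }
  }
  return lab;
}

// [[Rcpp::export]]
LogicalVector cpp_binary_morph(LogicalVector x, int d1, int d2, int d3,
                               IntegerMatrix offsets, bool dilate) {
  const int n = d1 * d2 * d3, m = offsets.nrow();
  LogicalVector out(n);
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        bool acc = !dilate;  // AND-identity for erode, OR-identity for dilate
        for (int t = 0; t < m; ++t) {
          int ii = i + offsets(t, 0), jj = j + offsets(t, 1), kk = k + offsets(t, 2);
          bool v = false;  // outside the volume counts as background
          if (ii >= 0 && jj >= 0 && kk >= 0 && ii < d1 && jj < d2 && kk < d3)
            v = x[lin(ii, jj, kk, d1, d2)];
          if (dilate) { if (v) { acc = true; break; } }
          else        { if (!v) { acc = false; break; } }
        }
        out[lin(i, j, k, d1, d2)] = acc;
      }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_gray_morph(NumericVector x, int d1, int d2, int d3,
                             IntegerMatrix offsets, bool dilate) {
  const int n = d1 * d2 * d3, m = offsets.nrow();
  NumericVector out(n);
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        double acc = dilate ? R_NegInf : R_PosInf;
        for (int t = 0; t < m; ++t) {
          int ii = i + offsets(t, 0), jj = j + offsets(t, 1), kk = k + offsets(t, 2);
          if (ii < 0 || jj < 0 || kk < 0 || ii >= d1 || jj >= d2 || kk >= d3)
            continue;  // border handled by ignoring out-of-volume taps
          double v = x[lin(ii, jj, kk, d1, d2)];
          if (dilate) { if (v > acc) acc = v; } else { if (v < acc) acc = v; }
        }
        out[lin(i, j, k, d1, d2)] = acc;
      }
  return out;
}

// Morphological reconstruction by erosion of `marker` above `mask`
// (marker >= mask expected). Gauss-Seidel forward/backward raster sweeps
// with 6-connectivity until stable.
// [[Rcpp::export]]
NumericVector cpp_reconstruct_erosion(NumericVector marker, NumericVector mask,
                                      int d1, int d2, int d3, int max_pass) {
  const int n = d1 * d2 * d3;
  NumericVector J = clone(marker);
  bool changed = true;
  int pass = 0;
  while (changed && pass < max_pass) {
    changed = false;
    ++pass;
    for (int dir = 0; dir < 2; ++dir) {
      int start = dir == 0 ? 0 : n - 1, stop = dir == 0 ? n : -1, step = dir == 0 ? 1 : -1;
      for (int s = start; s != stop; s += step) {
        int i = s % d1, rem = s / d1, j = rem % d2, k = rem / d2;
        double v = J[s];
        if (i > 0)      v = std::min(v, J[s - 1]);
        if (i < d1 - 1) v = std::min(v, J[s + 1]);
        if (j > 0)      v = std::min(v, J[s - d1]);
        if (j < d2 - 1) v = std::min(v, J[s + d1]);
        if (k > 0)      v = std::min(v, J[s - d1 * d2]);
        if (k < d3 - 1) v = std::min(v, J[s + d1 * d2]);
        v = std::max(v, mask[s]);
        if (v != J[s]) { J[s] = v; changed = true; }
      }
    }
  }
  return J;
}

// Seeded region growing: 6-connected flood over voxels with intensity <= thr.
// [[Rcpp::export]]
LogicalVector cpp_region_grow(NumericVector vol, int d1, int d2, int d3,
                              IntegerVector seeds, double thr) {
  const int n = d1 * d2 * d3;
  LogicalVector out(n, false);
  std::vector<int> stack;
  for (int t = 0; t < seeds.size(); ++t) {
    int s = seeds[t];
    if (s < 0 || s >= n) stop("seed index out of range");
    if (vol[s] <= thr && !out[s]) { out[s] = true; stack.push_back(s); }
  }
  while (!stack.empty()) {
    int cur = stack.back(); stack.pop_back();
    int i = cur % d1, rem = cur / d1, j = rem % d2, k = rem / d2;
    const int di[6] = {1, -1, 0, 0, 0, 0};
    const int dj[6] = {0, 0, 1, -1, 0, 0};
    const int dk[6] = {0, 0, 0, 0, 1, -1};
    for (int t = 0; t < 6; ++t) {
      int ii = i + di[t], jj = j + dj[t], kk = k + dk[t];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= d1 || jj >= d2 || kk >= d3) continue;
      int q = lin(ii, jj, kk, d1, d2);
      if (!out[q] && vol[q] <= thr) { out[q] = true; stack.push_back(q); }
    }
  }
  return out;
}

// Per-axial-slice hole filling. Volumes are (z, y, x); a slice is fixed first
// index. Background 4-connected in (y, x) and reachable from the slice border
// stays background; enclosed background becomes foreground.
// [[Rcpp::export]]
LogicalVector cpp_fill_holes_slices(LogicalVector mask, int d1, int d2, int d3) {
  LogicalVector out = clone(mask);
  std::vector<char> vis((size_t)d2 * d3);
  std::vector<int> stack;
  for (int z = 0; z < d1; ++z) {
    std::fill(vis.begin(), vis.end(), 0);
    stack.clear();
    for (int j = 0; j < d2; ++j)
      for (int k = 0; k < d3; ++k) {
        if (j != 0 && j != d2 - 1 && k != 0 && k != d3 - 1) continue;
        int p = j + d2 * k;
        if (!mask[lin(z, j, k, d1, d2)] && !vis[p]) { vis[p] = 1; stack.push_back(p); }
      }
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      int j = cur % d2, k = cur / d2;
      const int dj[4] = {1, -1, 0, 0};
      const int dk[4] = {0, 0, 1, -1};
      for (int t = 0; t < 4; ++t) {
        int jj = j + dj[t], kk = k + dk[t];
        if (jj < 0 || kk < 0 || jj >= d2 || kk >= d3) continue;
        int p = jj + d2 * kk;
        if (!vis[p] && !mask[lin(z, jj, kk, d1, d2)]) { vis[p] = 1; stack.push_back(p); }
      }
    }
    for (int j = 0; j < d2; ++j)
      for (int k = 0; k < d3; ++k)
        if (!mask[lin(z, j, k, d1, d2)] && !vis[j + d2 * k])
          out[lin(z, j, k, d1, d2)] = true;
  }
  return out;
}
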