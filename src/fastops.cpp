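#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Pixel-level kernels for classified-raster post-processing and k-means
// assignment. Rasters are integer matrices in column-major R layout; class
// labels are small positive integers, NA_INTEGER or `nodata` marks no-data.

// [[Rcpp::export]]
IntegerVector nn_assign_cpp(NumericMatrix x, NumericMatrix centers) {
  const int n = x.nrow(), d = x.ncol(), k = centers.nrow();
  IntegerVector out(n);
  const double* px = REAL(x);
  const double* pc = REAL(centers);
  std::vector<double> row(d);
  for (int i = 0; i < n; ++i) {
    for (int c = 0; c < d; ++c) row[c] = px[i + (R_xlen_t)c * n];
    double best = std::numeric_limits<double>::max();
    int bj = 0;
    for (int j = 0; j < k; ++j) {
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        double diff = row[c] - pc[j + (R_xlen_t)c * k];
        s += diff * diff;
        if (s >= best) break;
      }
      if (s < best) { best = s; bj = j; }
    }
    out[i] = bj + 1;
  }
  return out;
}

// Strict-majority vote in the 3x3 (or plus-shaped) neighbourhood, centre
// included; pixel kept when no strict majority. NA neighbours are ignored.
// [[Rcpp::export]]
IntegerMatrix majority_filter_cpp(IntegerMatrix m, int nclass, bool eight) {
  const int nr = m.nrow(), nc = m.ncol();
  IntegerMatrix out(nr, nc);
  std::vector<int> cnt(nclass + 1);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int v = m(i, j);
      if (v == NA_INTEGER) { out(i, j) = NA_INTEGER; continue; }
      std::fill(cnt.begin(), cnt.end(), 0);
      int tot = 0;
      for (int dj = -1; dj <= 1; ++dj) {
        for (int di = -1; di <= 1; ++di) {
          if (!eight && di != 0 && dj != 0) continue;
          int ii = i + di, jj = j + dj;
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          int w = m(ii, jj);
          if (w == NA_INTEGER || w < 1 || w > nclass) continue;
          ++cnt[w]; ++tot;
        }
      }
      int arg = v;
      // strict majority: > half of valid neighbourhood
      for (int c = 1; c <= nclass; ++c) {
        if (2 * cnt[c] > tot) { arg = c; break; }
      }
      out(i, j) = arg;
    }
  }
  return out;
}

// Connected-component labelling of a binary mask, 4- or 8-connectivity,
// iterative stack-based flood fill (no recursion). Labels start at 1.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, bool eight) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  std::vector<int> stack;
  int next = 0;
  const int di8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dj8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nnb = eight ? 8 : 4;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      stack.push_back(i + j * nr);
      lab(i, j) = next;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pi = p % nr, pj = p / nr;
        for (int q = 0; q < nnb; ++q) {
          int ii = pi + di8[q], jj = pj + dj8[q];
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          if (!mask(ii, jj) || lab(ii, jj) != 0) continue;
          lab(ii, jj) = next;
          stack.push_back(ii + jj * nr);
        }
      }
    }
  }
  return lab;
}

// One-dimensional squared EDT (Felzenszwalb & Huttenlocher lower envelope).
static void edt_1d(const std::vector<double>& f, std::vector<double>& d,
                   std::vector<int>& v, std::vector<double>& z) {
  const int n = (int)f.size();
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double diff = q - (double)v[k];
    d[q] = diff * diff + f[v[k]];
  }
}

// Exact squared Euclidean distance (in pixels) from every pixel to the
// nearest TRUE pixel of `mask`. Pixels of the mask get 0.
// [[Rcpp::export]]
NumericMatrix edt_sq_cpp(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const double INF = 1e18;
  NumericMatrix d(nr, nc);
  // columns first
  {
    std::vector<double> f(nr), dd(nr), z(nr + 1);
    std::vector<int> v(nr);
    for (int j = 0; j < nc; ++j) {
      for (int i = 0; i < nr; ++i) f[i] = mask(i, j) ? 0.0 : INF;
      edt_1d(f, dd, v, z);
      for (int i = 0; i < nr; ++i) d(i, j) = dd[i];
    }
  }
  // then rows
  {
    std::vector<double> f(nc), dd(nc), z(nc + 1);
    std::vector<int> v(nc);
    for (int i = 0; i < nr; ++i) {
      for (int j = 0; j < nc; ++j) f[j] = d(i, j);
      edt_1d(f, dd, v, z);
      for (int j = 0; j < nc; ++j) d(i, j) = dd[j];
    }
  }
  return d;
}

// 3x3 binary dilation / erosion (box structuring element).
// [[Rcpp::export]]
LogicalMatrix morph3_cpp(LogicalMatrix mask, bool dilate) {
  const int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      bool acc = !dilate;
      for (int dj = -1; dj <= 1 && (dilate ? !acc : acc); ++dj) {
        for (int di = -1; di <= 1; ++di) {
          int ii = i + di, jj = j + dj;
          bool v;
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) {
            v = false;       // outside the raster counts as background
          } else {
            v = mask(ii, jj);
          }
          if (dilate) { if (v) { acc = true; break; } }
          else        { if (!v) { acc = false; break; } }
        }
      }
      out(i, j) = acc;
    }
  }
  return out;
}

// Component areas in pixels for a labelled matrix (label 0 = background).
// [[Rcpp::export]]
NumericVector component_sizes_cpp(IntegerMatrix lab, int nlab) {
  NumericVector out(nlab);
  const int n = lab.nrow() * lab.ncol();
  for (int p = 0; p < n; ++p) {
    int v = lab[p];
    if (v > 0) out[v - 1] += 1.0;
  }
  return out;
}
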