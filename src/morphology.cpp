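#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Pixel-level primitives for nucleus segmentation: connected-component
// labelling, exact Euclidean distance transform, marker-controlled watershed,
// separable Gaussian smoothing and a square max filter. All matrices are
// column-major (R layout); coordinates are (row, col).

static const int DR8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
static const int DR4[4] = {-1, 0, 0, 1};
static const int DC4[4] = {-1, 1, -1, 0};

// Connected components of a logical mask, labels 1..N in raster scan order
// of each component's first-seen pixel. connectivity: 4 or 8.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask, int connectivity = 8) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  const int *dr = (connectivity == 4) ? DR4 : DR8;
  const int *dc = (connectivity == 4) ? DC4 : DC8;
  int nd = (connectivity == 4) ? 4 : 8;
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.clear();
      stack.push_back(r + c * nr);
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int rr = idx % nr, cc = idx / nr;
        for (int k = 0; k < nd; ++k) {
          int r2 = rr + dr[k], c2 = cc + dc[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            stack.push_back(r2 + c2 * nr);
          }
        }
      }
    }
  }
  return lab;
}

// 1-D squared distance transform (Felzenszwalb & Huttenlocher).
static void dt1d(const std::vector<double> &f, std::vector<double> &d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
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
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// Exact Euclidean distance transform: distance from each foreground pixel to
// the nearest background pixel (0 on background).
// [[Rcpp::export]]
NumericMatrix cpp_edt(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  NumericMatrix out(nr, nc);
  const double INF = 1e18;
  // pass 1: columns
  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  NumericMatrix tmp(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) f[r] = mask(r, c) ? INF : 0.0;
    dt1d(f, d, nr);
    for (int r = 0; r < nr; ++r) tmp(r, c) = d[r];
  }
  // pass 2: rows
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) f[c] = tmp(r, c);
    dt1d(f, d, nc);
    for (int c = 0; c < nc; ++c) out(r, c) = std::sqrt(d[c]);
  }
  return out;
}

struct QItem {
  double elev;
  long order;
  int idx;
};
struct QCmp {
  bool operator()(const QItem &a, const QItem &b) const {
    if (a.elev != b.elev) return a.elev > b.elev;  // lowest elevation first
    return a.order > b.order;                      // FIFO tie-break
  }
};

// Marker-controlled watershed flood of `elevation` restricted to `mask`.
// Markers are nonzero seed labels; every masked pixel ends up with the label
// of the basin that reaches it first (no watershed-line pixels), so the
// union of output labels equals the input mask exactly.
// [[Rcpp::export]]
IntegerMatrix cpp_watershed(NumericMatrix elevation, IntegerMatrix markers,
                            LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::priority_queue<QItem, std::vector<QItem>, QCmp> pq;
  long order = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (markers(r, c) != 0 && mask(r, c)) {
        lab(r, c) = markers(r, c);
        pq.push({elevation(r, c), order++, r + c * nr});
      }
  while (!pq.empty()) {
    QItem it = pq.top();
    pq.pop();
    int r = it.idx % nr, c = it.idx / nr;
    int l = lab(r, c);
    for (int k = 0; k < 8; ++k) {
      int r2 = r + DR8[k], c2 = c + DC8[k];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      if (mask(r2, c2) && lab(r2, c2) == 0) {
        lab(r2, c2) = l;
        pq.push({elevation(r2, c2), order++, r2 + c2 * nr});
      }
    }
  }
  return lab;
}

// Separable Gaussian smoothing with reflected boundaries.
// [[Rcpp::export]]
NumericMatrix cpp_gaussian_blur(NumericMatrix x, double sigma) {
  int nr = x.nrow(), nc = x.ncol();
  if (sigma <= 0) return clone(x);
  int rad = (int)std::ceil(3.0 * sigma);
  std::vector<double> ker(2 * rad + 1);
  double s = 0;
  for (int i = -rad; i <= rad; ++i) {
    ker[i + rad] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += ker[i + rad];
  }
  for (double &k : ker) k /= s;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double acc = 0;
      for (int i = -rad; i <= rad; ++i) {
        int rr = r + i;
        if (rr < 0) rr = -rr - 1;
        if (rr >= nr) rr = 2 * nr - rr - 1;
        acc += ker[i + rad] * x(rr, c);
      }
      tmp(r, c) = acc;
    }
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double acc = 0;
      for (int i = -rad; i <= rad; ++i) {
        int cc = c + i;
        if (cc < 0) cc = -cc - 1;
        if (cc >= nc) cc = 2 * nc - cc - 1;
        acc += ker[i + rad] * tmp(r, cc);
      }
      out(r, c) = acc;
    }
  return out;
}

// Square (Chebyshev) max filter of radius `rad`.
// [[Rcpp::export]]
NumericMatrix cpp_max_filter(NumericMatrix x, int rad) {
  int nr = x.nrow(), nc = x.ncol();
  NumericMatrix tmp(nr, nc), out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double m = -std::numeric_limits<double>::infinity();
      for (int i = std::max(0, r - rad); i <= std::min(nr - 1, r + rad); ++i)
        if (x(i, c) > m) m = x(i, c);
      tmp(r, c) = m;
    }
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double m = -std::numeric_limits<double>::infinity();
      for (int i = std::max(0, c - rad); i <= std::min(nc - 1, c + rad); ++i)
        if (tmp(r, i) > m) m = tmp(r, i);
      out(r, c) = m;
    }
  return out;
}
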