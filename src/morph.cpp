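#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>
using namespace Rcpp;

// Pixel-grid primitives shared by the segmentation and morphology layers.
// All matrices follow R's column-major storage; "raster order" below means
// row-major scanning (row 0 left to right, then row 1, ...), which fixes a
// canonical label numbering independent of flood-fill internals.

// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix fg, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int nr = fg.nrow(), nc = fg.ncol();
  IntegerMatrix lab(nr, nc);
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 0, 0, 1};
  const int dc4[4] = {0, -1, 1, 0};
  const int *dr = connectivity == 8 ? dr8 : dr4;
  const int *dc = connectivity == 8 ? dc8 : dc4;
  const int nn = connectivity;
  int next = 0;
  std::vector<int> stack;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (!fg(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.clear();
      stack.push_back(r + c * nr);
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int cr = idx % nr, cc = idx / nr;
        for (int k = 0; k < nn; ++k) {
          int r2 = cr + dr[k], c2 = cc + dc[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (fg(r2, c2) && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            stack.push_back(r2 + c2 * nr);
          }
        }
      }
    }
  }
  return lab;
}

// Felzenszwalb & Huttenlocher 1-D squared distance transform.
static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z, int n) {
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Squared Euclidean distance from each TRUE pixel to the nearest FALSE
// pixel. Everything outside the image border counts as FALSE, so erosion
// derived from this transform is conservative at the image edge.
// [[Rcpp::export]]
NumericMatrix cpp_edt_sq(LogicalMatrix fg) {
  const int nr = fg.nrow() + 2, nc = fg.ncol() + 2;
  const double INF = 1e20;
  std::vector<double> g(nr * nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      bool inside = r > 0 && r < nr - 1 && c > 0 && c < nc - 1 &&
                    fg(r - 1, c - 1);
      g[r + c * nr] = inside ? INF : 0.0;
    }
  int nmax = nr > nc ? nr : nc;
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // columns
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) f[r] = g[r + c * nr];
    dt1d(f, d, v, z, nr);
    for (int r = 0; r < nr; ++r) g[r + c * nr] = d[r];
  }
  // rows
  NumericMatrix out(nr - 2, nc - 2);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) f[c] = g[r + c * nr];
    dt1d(f, d, v, z, nc);
    if (r > 0 && r < nr - 1)
      for (int c = 1; c < nc - 1; ++c) out(r - 1, c - 1) = d[c];
  }
  return out;
}

// Separable convolution with mirrored (symmetric) borders; interior
// pixels take a branch-free fast path.
// [[Rcpp::export]]
NumericMatrix cpp_convolve_sep(NumericMatrix img, NumericVector kernel) {
  const int nr = img.nrow(), nc = img.ncol(), kl = kernel.size();
  const int h = kl / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  const double *src = img.begin();
  const double *kw = kernel.begin();
  double *dst = tmp.begin();
  // vertical pass (contiguous in memory)
  for (int c = 0; c < nc; ++c) {
    const double *col = src + (size_t)c * nr;
    double *ocol = dst + (size_t)c * nr;
    int r = 0;
    for (; r < h && r < nr; ++r) {
      double s = 0;
      for (int k = 0; k < kl; ++k) {
        int rr = r + k - h;
        if (rr < 0) rr = -rr - 1;
        if (rr >= nr) rr = 2 * nr - rr - 1;
        s += col[rr] * kw[k];
      }
      ocol[r] = s;
    }
    for (; r < nr - h; ++r) {
      double s = 0;
      const double *p = col + r - h;
      for (int k = 0; k < kl; ++k) s += p[k] * kw[k];
      ocol[r] = s;
    }
    for (; r < nr; ++r) {
      double s = 0;
      for (int k = 0; k < kl; ++k) {
        int rr = r + k - h;
        if (rr < 0) rr = -rr - 1;
        if (rr >= nr) rr = 2 * nr - rr - 1;
        s += col[rr] * kw[k];
      }
      ocol[r] = s;
    }
  }
  // horizontal pass
  const double *tsrc = tmp.begin();
  double *odst = out.begin();
  for (int c = 0; c < nc; ++c) {
    bool interior = c >= h && c < nc - h;
    double *ocol = odst + (size_t)c * nr;
    if (interior) {
      const double *base = tsrc + (size_t)(c - h) * nr;
      for (int r = 0; r < nr; ++r) {
        double s = 0;
        const double *p = base + r;
        for (int k = 0; k < kl; ++k) s += p[(size_t)k * nr] * kw[k];
        ocol[r] = s;
      }
    } else {
      for (int r = 0; r < nr; ++r) {
        double s = 0;
        for (int k = 0; k < kl; ++k) {
          int cc = c + k - h;
          if (cc < 0) cc = -cc - 1;
          if (cc >= nc) cc = 2 * nc - cc - 1;
          s += tsrc[r + (size_t)cc * nr] * kw[k];
        }
        ocol[r] = s;
      }
    }
  }
  return out;
}

// Binary erosion by a square structuring element of half-width r
// (window (2r+1)^2); pixels outside the image are background.
// [[Rcpp::export]]
LogicalMatrix cpp_erode_square(LogicalMatrix fg, int r) {
  const int nr = fg.nrow(), nc = fg.ncol();
  LogicalMatrix tmp(nr, nc), out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int row = 0; row < nr; ++row) {
      bool all = true;
      for (int k = -r; k <= r && all; ++k) {
        int rr = row + k;
        if (rr < 0 || rr >= nr || !fg(rr, c)) all = false;
      }
      tmp(row, c) = all;
    }
  for (int c = 0; c < nc; ++c)
    for (int row = 0; row < nr; ++row) {
      bool all = true;
      for (int k = -r; k <= r && all; ++k) {
        int cc = c + k;
        if (cc < 0 || cc >= nc || !tmp(row, cc)) all = false;
      }
      out(row, c) = all;
    }
  return out;
}

struct WsNode {
  double elev;
  long order;
  int idx;
  int label;
};
struct WsCmp {
  bool operator()(const WsNode &a, const WsNode &b) const {
    if (a.elev != b.elev) return a.elev < b.elev; // max-heap on elevation
    return a.order > b.order;                     // FIFO tie-break
  }
};

// Marker-controlled watershed on an elevation map (descending flood),
// constrained so labels never cross connected-component boundaries of
// `comp`. Used to split touching cells on the distance transform.
// [[Rcpp::export]]
IntegerMatrix cpp_marker_watershed(IntegerMatrix comp, NumericMatrix elev,
                                   IntegerMatrix markers) {
  const int nr = comp.nrow(), nc = comp.ncol();
  IntegerMatrix out(nr, nc);
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  long order = 0;
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c)
      if (markers(r, c) > 0) {
        out(r, c) = markers(r, c);
        pq.push({elev(r, c), order++, r + c * nr, markers(r, c)});
      }
  const int dr[4] = {-1, 0, 0, 1};
  const int dc[4] = {0, -1, 1, 0};
  while (!pq.empty()) {
    WsNode nd = pq.top();
    pq.pop();
    int cr = nd.idx % nr, cc = nd.idx / nr;
    for (int k = 0; k < 4; ++k) {
      int r2 = cr + dr[k], c2 = cc + dc[k];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      if (comp(r2, c2) == comp(cr, cc) && comp(r2, c2) > 0 &&
          out(r2, c2) == 0) {
        out(r2, c2) = nd.label;
        pq.push({elev(r2, c2), order++, r2 + c2 * nr, nd.label});
      }
    }
  }
  return out;
}
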