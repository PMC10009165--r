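#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Low-level raster primitives used by the segmentation and feature modules.
// All matrices are column-major (R layout); coordinates returned to R are
// 1-based (row, col).

// ---------------------------------------------------------------------------
// Separable Gaussian blur, "reflect" (half-sample symmetric) padding.
// Kernel truncated at 4 sigma.
// ---------------------------------------------------------------------------

static inline int reflect_idx(int i, int n) {
  // half-sample symmetric: ... c b a | a b c ... | c b a ...
  if (n == 1) return 0;
  int period = 2 * n;
  i = ((i % period) + period) % period;
  return (i < n) ? i : (period - 1 - i);
}

// [[Rcpp::export]]
NumericMatrix cpp_gaussian_blur(const NumericMatrix& img, double sigma) {
  int nr = img.nrow(), nc = img.ncol();
  int rad = (int)std::ceil(4.0 * sigma);
  std::vector<double> k(2 * rad + 1);
  double s = 0.0;
  for (int i = -rad; i <= rad; ++i) {
    k[i + rad] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += k[i + rad];
  }
  for (double& v : k) v /= s;

  NumericMatrix tmp(nr, nc), out(nr, nc);
  // blur along rows (within each column)
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double acc = 0.0;
      for (int i = -rad; i <= rad; ++i)
        acc += k[i + rad] * img(reflect_idx(r + i, nr), c);
      tmp(r, c) = acc;
    }
  // blur along columns (within each row)
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double acc = 0.0;
      for (int i = -rad; i <= rad; ++i)
        acc += k[i + rad] * tmp(r, reflect_idx(c + i, nc));
      out(r, c) = acc;
    }
  return out;
}

// ---------------------------------------------------------------------------
// Binary erosion / dilation with an arbitrary structuring element (odd dims,
// origin at center).  Outside the image counts as background.
// ---------------------------------------------------------------------------

static std::vector<std::pair<int, int> > se_offsets(const LogicalMatrix& se) {
  int hr = se.nrow() / 2, hc = se.ncol() / 2;
  std::vector<std::pair<int, int> > off;
  for (int c = 0; c < se.ncol(); ++c)
    for (int r = 0; r < se.nrow(); ++r)
      if (se(r, c)) off.push_back(std::make_pair(r - hr, c - hc));
  return off;
}

// [[Rcpp::export]]
LogicalMatrix cpp_erode(const LogicalMatrix& mask, const LogicalMatrix& se) {
  int nr = mask.nrow(), nc = mask.ncol();
  std::vector<std::pair<int, int> > off = se_offsets(se);
  LogicalMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      bool all = true;
      for (size_t i = 0; i < off.size() && all; ++i) {
        int rr = r + off[i].first, cc = c + off[i].second;
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc || !mask(rr, cc)) all = false;
      }
      out(r, c) = all;
    }
  return out;
}

// [[Rcpp::export]]
LogicalMatrix cpp_dilate(const LogicalMatrix& mask, const LogicalMatrix& se) {
  int nr = mask.nrow(), nc = mask.ncol();
  std::vector<std::pair<int, int> > off = se_offsets(se);
  LogicalMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      for (size_t i = 0; i < off.size(); ++i) {
        int rr = r - off[i].first, cc = c - off[i].second;
        if (rr >= 0 && rr < nr && cc >= 0 && cc < nc) out(rr, cc) = true;
      }
    }
  return out;
}

// ---------------------------------------------------------------------------
// Connected-component labeling, 4- or 8-connectivity, BFS, raster order ids.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix cpp_label(const LogicalMatrix& mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  int ndir = (connectivity == 8) ? 8 : 4;
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c)) continue;
      lab(r, c) = ++next;
      q.push(std::make_pair(r, c));
      while (!q.empty()) {
        std::pair<int, int> p = q.front(); q.pop();
        for (int d = 0; d < ndir; ++d) {
          int rr = p.first + dr8[d], cc = p.second + dc8[d];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (mask(rr, cc) && !lab(rr, cc)) {
            lab(rr, cc) = next;
            q.push(std::make_pair(rr, cc));
          }
        }
      }
    }
  return lab;
}

// ---------------------------------------------------------------------------
// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher).
// Distance from every pixel to the nearest TRUE pixel; pixels in an image
// with no TRUE pixel get a huge value (>= 1e20).
// ---------------------------------------------------------------------------

static const double DT_INF = 1e20;

static void dt1d(std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -DT_INF;
  z[1] = DT_INF;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = DT_INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = (double)q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_sqedt(const LogicalMatrix& feature) {
  int nr = feature.nrow(), nc = feature.ncol();
  NumericMatrix g(nr, nc);
  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  // columns first
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) f[r] = feature(r, c) ? 0.0 : DT_INF;
    dt1d(f, d, nr);
    for (int r = 0; r < nr; ++r) g(r, c) = d[r];
  }
  // then rows
  NumericMatrix out(nr, nc);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) f[c] = g(r, c);
    dt1d(f, d, nc);
    for (int c = 0; c < nc; ++c) out(r, c) = std::min(d[c], DT_INF);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Moore-neighbor boundary tracing with Jacob's stopping criterion.
// Traces the outer boundary of the 8-connected object in `mask` (which must
// contain a single object; holes are ignored).  Returns 1-based (row, col).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix cpp_trace_boundary(const LogicalMatrix& mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  // clockwise on screen (row down): E, SE, S, SW, W, NW, N, NE
  const int dr[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  const int dc[8] = {1, 1, 0, -1, -1, -1, 0, 1};

  int sr = -1, sc = -1, npix = 0;
  for (int r = 0; r < nr && sr < 0; ++r)
    for (int c = 0; c < nc; ++c)
      if (mask(r, c)) { sr = r; sc = c; break; }
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) if (mask(r, c)) ++npix;
  if (sr < 0) return IntegerMatrix(0, 2);

  // isolated pixel?
  bool lone = true;
  for (int d = 0; d < 8 && lone; ++d) {
    int rr = sr + dr[d], cc = sc + dc[d];
    if (rr >= 0 && rr < nr && cc >= 0 && cc < nc && mask(rr, cc)) lone = false;
  }
  if (lone) {
    IntegerMatrix out(1, 2);
    out(0, 0) = sr + 1; out(0, 1) = sc + 1;
    return out;
  }

  std::vector<int> rows, cols;
  int cr = sr, cc = sc;
  int back = 4; // backtrack direction (towards W): start pixel found by raster
                // scan so its N row and W neighbor are background
  rows.push_back(cr); cols.push_back(cc);
  int first_move = -1;
  int maxit = 8 * npix + 16;
  for (int it = 0; it < maxit; ++it) {
    int found = -1;
    for (int i = 1; i <= 8; ++i) {
      int d = (back + i) % 8;
      int rr = cr + dr[d], c2 = cc + dc[d];
      if (rr >= 0 && rr < nr && c2 >= 0 && c2 < nc && mask(rr, c2)) {
        found = d;
        break;
      }
    }
    if (found < 0) break; // cannot happen for a connected object with >1 px
    // Jacob's criterion: stop when about to leave the start pixel in the
    // same direction as the initial move.
    if (cr == sr && cc == sc && first_move >= 0 && found == first_move) break;
    if (first_move < 0) first_move = found;
    int nrow_ = cr + dr[found], ncol_ = cc + dc[found];
    // new backtrack: the neighbor just before `found` in the clockwise scan,
    // expressed as a direction from the *new* current pixel
    int prev_d = (found + 7) % 8;
    int br = cr + dr[prev_d], bc = cc + dc[prev_d];
    cr = nrow_; cc = ncol_;
    // direction from new current to backtrack cell
    back = 0;
    for (int d = 0; d < 8; ++d)
      if (cr + dr[d] == br && cc + dc[d] == bc) { back = d; break; }
    rows.push_back(cr); cols.push_back(cc);
  }
  // drop a trailing repeat of the start pixel, if any
  while (rows.size() > 1 && rows.back() == sr && cols.back() == sc) {
    rows.pop_back(); cols.pop_back();
  }
  IntegerMatrix out(rows.size(), 2);
  for (size_t i = 0; i < rows.size(); ++i) {
    out(i, 0) = rows[i] + 1;
    out(i, 1) = cols[i] + 1;
  }
  return out;
}
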