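#include <Rcpp.h>
#include <queue>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Low-level raster primitives. Conventions shared with the R code:
// matrices are indexed [row, col] = [y + 1, x + 1]; exported point sets are
// 0-based (x, y) pixel coordinates; foreground is 8-connected, background
// 4-connected.

// [[Rcpp::export(name = ".cpp_median3x3")]]
NumericMatrix cpp_median3x3(const NumericMatrix& img) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  double buf[9];
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      int k = 0;
      for (int dx = -1; dx <= 1; ++dx) {
        int xx = std::min(std::max(x + dx, 0), W - 1);  // edge replication
        for (int dy = -1; dy <= 1; ++dy) {
          int yy = std::min(std::max(y + dy, 0), H - 1);
          buf[k++] = img(yy, xx);
        }
      }
      std::nth_element(buf, buf + 4, buf + 9);
      out(y, x) = buf[4];
    }
  }
  return out;
}

// 8-connected component labelling by BFS; labels numbered 1.. in raster
// (row-major, top-left first) order of first encounter.
// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerMatrix cpp_label_components(const LogicalMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int y = 0; y < H; ++y) {
    for (int x = 0; x < W; ++x) {
      if (!mask(y, x) || lab(y, x)) continue;
      lab(y, x) = ++next;
      q.push(std::make_pair(y, x));
      while (!q.empty()) {
        int cy = q.front().first, cx = q.front().second;
        q.pop();
        for (int dy = -1; dy <= 1; ++dy) {
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dy && !dx) continue;
            int ny = cy + dy, nx = cx + dx;
            if (ny < 0 || ny >= H || nx < 0 || nx >= W) continue;
            if (mask(ny, nx) && !lab(ny, nx)) {
              lab(ny, nx) = next;
              q.push(std::make_pair(ny, nx));
            }
          }
        }
      }
    }
  }
  return lab;
}

// Moore-neighbour border following with Jacob's stopping criterion: outer
// boundary of the (single) 8-connected component containing the raster-first
// foreground pixel. Returns an n x 2 matrix of 0-based (x, y), orientation
// counter-clockwise in the mathematical sense (positive shoelace area with y
// measured upwards).
// [[Rcpp::export(name = ".cpp_trace_contour")]]
IntegerMatrix cpp_trace_contour(const LogicalMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  int sy = -1, sx = -1;
  for (int y = 0; y < H && sy < 0; ++y)
    for (int x = 0; x < W; ++x)
      if (mask(y, x)) { sy = y; sx = x; break; }
  if (sy < 0) stop("empty mask");

  // clockwise Moore neighbourhood in image coordinates, starting West
  const int DY[8] = { 0, -1, -1, -1,  0,  1, 1, 1 };
  const int DX[8] = { -1, -1,  0,  1,  1,  1, 0, -1 };
  std::vector<int> xs, ys;
  int cy = sy, cx = sx;
  // `back` = direction index from the current pixel to its backtrack
  // (background) pixel; the raster-first pixel always has background West.
  int back = 0;
  xs.push_back(cx); ys.push_back(cy);
  int guard = 8 * H * W + 8;
  while (guard-- > 0) {
    int found = -1;
    for (int i = 1; i <= 8; ++i) {
      int d = (back + i) % 8;
      int ny = cy + DY[d], nx = cx + DX[d];
      if (ny >= 0 && ny < H && nx >= 0 && nx < W && mask(ny, nx)) { found = d; break; }
    }
    if (found < 0) break;  // isolated pixel
    cy += DY[found]; cx += DX[found];
    // the neighbour examined just before `found` is background; direction
    // from the new pixel to it reduces to this closed form (consecutive
    // clockwise Moore neighbours are king-adjacent)
    back = (2 * (found / 2) + 6) % 8;
    // Jacob's stopping criterion: start pixel re-entered in the start state
    if (cy == sy && cx == sx && back == 0) break;
    xs.push_back(cx); ys.push_back(cy);
  }
  if (guard <= 0) stop("contour tracing failed to close");
  // drop duplicated closing point if present
  int n = xs.size();
  if (n > 1 && xs[n - 1] == xs[0] && ys[n - 1] == ys[0]) { xs.pop_back(); ys.pop_back(); n--; }
  // enforce counter-clockwise (positive shoelace with y upwards)
  double area2 = 0.0;
  for (int i = 0; i < n; ++i) {
    int j = (i + 1) % n;
    area2 += (double)xs[i] * (-(double)ys[j]) - (double)xs[j] * (-(double)ys[i]);
  }
  IntegerMatrix out(n, 2);
  if (area2 < 0) {
    for (int i = 0; i < n; ++i) { out(i, 0) = xs[n - 1 - i]; out(i, 1) = ys[n - 1 - i]; }
  } else {
    for (int i = 0; i < n; ++i) { out(i, 0) = xs[i]; out(i, 1) = ys[i]; }
  }
  return out;
}

// Fill the region bounded by a closed 8-connected pixel contour: 4-connected
// flood from the frame border over non-contour pixels; everything unreached
// (plus the contour itself) is interior.
// [[Rcpp::export(name = ".cpp_fill_contour")]]
LogicalMatrix cpp_fill_contour(const IntegerMatrix& pts, int H, int W) {
  LogicalMatrix on(H, W), outside(H, W);
  for (int i = 0; i < pts.nrow(); ++i) {
    int x = pts(i, 0), y = pts(i, 1);
    if (x < 0 || x >= W || y < 0 || y >= H) stop("contour point outside grid");
    on(y, x) = true;
  }
  std::queue<std::pair<int, int> > q;
  for (int x = 0; x < W; ++x) {
    if (!on(0, x)) { outside(0, x) = true; q.push(std::make_pair(0, x)); }
    if (!on(H - 1, x) && !outside(H - 1, x)) { outside(H - 1, x) = true; q.push(std::make_pair(H - 1, x)); }
  }
  for (int y = 0; y < H; ++y) {
    if (!on(y, 0) && !outside(y, 0)) { outside(y, 0) = true; q.push(std::make_pair(y, 0)); }
    if (!on(y, W - 1) && !outside(y, W - 1)) { outside(y, W - 1) = true; q.push(std::make_pair(y, W - 1)); }
  }
  const int DY[4] = { -1, 1, 0, 0 }, DX[4] = { 0, 0, -1, 1 };
  while (!q.empty()) {
    int cy = q.front().first, cx = q.front().second;
    q.pop();
    for (int d = 0; d < 4; ++d) {
      int ny = cy + DY[d], nx = cx + DX[d];
      if (ny < 0 || ny >= H || nx < 0 || nx >= W) continue;
      if (!on(ny, nx) && !outside(ny, nx)) {
        outside(ny, nx) = true;
        q.push(std::make_pair(ny, nx));
      }
    }
  }
  LogicalMatrix fill(H, W);
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x)
      fill(y, x) = !outside(y, x);
  return fill;
}

// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher): distance
// from each foreground pixel to the nearest background pixel centre; pixels
// outside the image count as background (virtual one-pixel border).
static void dt1d(const std::vector<double>& f, std::vector<double>& d) {
  const int n = f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0; z[0] = -1e30; z[1] = 1e30;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) / (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k; v[k] = q; z[k] = s; z[k + 1] = 1e30;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export(name = ".cpp_edt")]]
NumericMatrix cpp_edt(const LogicalMatrix& mask) {
  const int H = mask.nrow() + 2, W = mask.ncol() + 2;  // virtual bg border
  std::vector<double> g(H * W);
  const double INF = 1e30;
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y) {
      bool fg = (x > 0 && y > 0 && x < W - 1 && y < H - 1) && mask(y - 1, x - 1);
      g[x * H + y] = fg ? INF : 0.0;
    }
  std::vector<double> fc(H), dc(H);
  for (int x = 0; x < W; ++x) {  // columns
    for (int y = 0; y < H; ++y) fc[y] = g[x * H + y];
    dt1d(fc, dc);
    for (int y = 0; y < H; ++y) g[x * H + y] = dc[y];
  }
  NumericMatrix out(H - 2, W - 2);
  std::vector<double> fr(W), dr(W);
  for (int y = 0; y < H; ++y) {  // rows
    for (int x = 0; x < W; ++x) fr[x] = g[x * H + y];
    dt1d(fr, dr);
    if (y > 0 && y < H - 1)
      for (int x = 1; x < W - 1; ++x) out(y - 1, x - 1) = std::sqrt(dr[x]);
  }
  return out;
}

// Per-channel affine maps used by the batch-norm layers: single-pass, no
// large temporaries. X is (m x C); a, b, ... are length-C.

// [[Rcpp::export(name = ".cpp_col_affine")]]
NumericMatrix cpp_col_affine(const NumericMatrix& X, const NumericVector& a,
                             const NumericVector& b) {
  const int m = X.nrow(), C = X.ncol();
  NumericMatrix out(m, C);
  for (int c = 0; c < C; ++c) {
    const double ac = a[c], bc = b[c];
    const double* xi = &X(0, c);
    double* oi = &out(0, c);
    for (int i = 0; i < m; ++i) oi[i] = xi[i] * ac + bc;
  }
  return out;
}

// A * sa[c] + B * sb[c] + sh[c]
// [[Rcpp::export(name = ".cpp_col_affine2")]]
NumericMatrix cpp_col_affine2(const NumericMatrix& A, const NumericMatrix& B,
                              const NumericVector& sa, const NumericVector& sb,
                              const NumericVector& sh) {
  const int m = A.nrow(), C = A.ncol();
  NumericMatrix out(m, C);
  for (int c = 0; c < C; ++c) {
    const double sac = sa[c], sbc = sb[c], shc = sh[c];
    const double* ai = &A(0, c);
    const double* bi = &B(0, c);
    double* oi = &out(0, c);
    for (int i = 0; i < m; ++i) oi[i] = ai[i] * sac + bi[i] * sbc + shc;
  }
  return out;
}

// ---- Welzl minimum enclosing circle ---------------------------------------
struct Circ { double x, y, r; };

static Circ circ2(double ax, double ay, double bx, double by) {
  Circ c;
  c.x = (ax + bx) / 2; c.y = (ay + by) / 2;
  c.r = std::hypot(ax - bx, ay - by) / 2;
  return c;
}
static Circ circ3(double ax, double ay, double bx, double by, double cx, double cy) {
  double A = bx - ax, B = by - ay, C = cx - ax, D = cy - ay;
  double E = A * (ax + bx) + B * (ay + by);
  double F = C * (ax + cx) + D * (ay + cy);
  double G = 2.0 * (A * (cy - by) - B * (cx - bx));
  Circ c;
  if (std::fabs(G) < 1e-12) {  // collinear: fall back to widest pair
    Circ c1 = circ2(ax, ay, bx, by), c2 = circ2(ax, ay, cx, cy), c3 = circ2(bx, by, cx, cy);
    c = c1;
    if (c2.r > c.r) c = c2;
    if (c3.r > c.r) c = c3;
    return c;
  }
  c.x = (D * E - B * F) / G;
  c.y = (A * F - C * E) / G;
  c.r = std::hypot(ax - c.x, ay - c.y);
  return c;
}
static bool inc(const Circ& c, double x, double y) {
  return std::hypot(x - c.x, y - c.y) <= c.r + 1e-9;
}

// Welzl's move-to-front algorithm (points pre-shuffled by the caller).
static Circ welzl(std::vector<std::pair<double, double> >& P, int n,
                  std::vector<std::pair<double, double> >& R) {
  if (n == 0 || R.size() == 3) {
    switch (R.size()) {
      case 0: { Circ c = { 0, 0, -1 }; return c; }
      case 1: { Circ c = { R[0].first, R[0].second, 0 }; return c; }
      case 2: return circ2(R[0].first, R[0].second, R[1].first, R[1].second);
      default: return circ3(R[0].first, R[0].second, R[1].first, R[1].second,
                            R[2].first, R[2].second);
    }
  }
  Circ c = welzl(P, n - 1, R);
  if (c.r >= 0 && inc(c, P[n - 1].first, P[n - 1].second)) return c;
  R.push_back(P[n - 1]);
  c = welzl(P, n - 1, R);
  R.pop_back();
  return c;
}

// [[Rcpp::export(name = ".cpp_min_enclosing_circle")]]
NumericVector cpp_min_enclosing_circle(const NumericMatrix& pts, const IntegerVector& order) {
  const int n = pts.nrow();
  if (n < 1) stop("need at least one point");
  std::vector<std::pair<double, double> > P(n), R;
  for (int i = 0; i < n; ++i) {
    int j = order[i] - 1;
    P[i] = std::make_pair(pts(j, 0), pts(j, 1));
  }
  Circ c = welzl(P, n, R);
  if (n == 1) { c.x = P[0].first; c.y = P[0].second; c.r = 0; }
  return NumericVector::create(c.x, c.y, c.r);
}
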