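#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Lookup table for K0 on a log-spaced grid: the kernel sums are O(N^2) and
// dominate the run time, so per-pair cost matters. Linear interpolation in
// u = log(x) keeps the absolute error below ~1e-7 (K0 is nearly linear in u
// for small x). Outside the table: series limit for x -> 0, 0 for large x.
namespace {

const double TWO_PI = 6.283185307179586476925286766559;
const double EULER_GAMMA = 0.57721566490153286060651209008240;

struct K0Table {
  double umin, umax, du;
  int n;
  std::vector<double> val;
  bool ready = false;
};

K0Table k0tab;

void build_k0_table() {
  if (k0tab.ready) return;
  k0tab.n = 32768;
  k0tab.umin = std::log(1e-8);
  k0tab.umax = std::log(60.0);
  k0tab.du = (k0tab.umax - k0tab.umin) / (k0tab.n - 1);
  k0tab.val.resize(k0tab.n);
  for (int i = 0; i < k0tab.n; ++i) {
    double x = std::exp(k0tab.umin + i * k0tab.du);
    k0tab.val[i] = R::bessel_k(x, 0.0, 1.0);
  }
  k0tab.ready = true;
}

inline double k0_fast(double x) {
  if (x >= 60.0) return 0.0;              // K0(60) ~ 2e-27
  if (x <= 1e-8) return -std::log(0.5 * x) - EULER_GAMMA;
  double u = std::log(x);
  double t = (u - k0tab.umin) / k0tab.du;
  int i = (int)t;
  if (i >= k0tab.n - 1) i = k0tab.n - 2;
  double f = t - i;
  return (1.0 - f) * k0tab.val[i] + f * k0tab.val[i + 1];
}

} // namespace

//' @name kernel-sums
//' @noRd

// Sum_j strength[j] * K0(k * |eval_i - src_j|) / (2*pi), skipping
// coincident pairs (the singular self term is added analytically in R).
// [[Rcpp::export]]
NumericVector cpp_k0_sum(NumericMatrix eval, NumericMatrix src,
                         NumericVector strength, double k) {
  build_k0_table();
  int ne = eval.nrow(), ns = src.nrow();
  NumericVector out(ne);
  std::vector<double> sx(ns), sy(ns), st(ns);
  for (int j = 0; j < ns; ++j) {
    sx[j] = src(j, 0); sy[j] = src(j, 1); st[j] = strength[j];
  }
  for (int i = 0; i < ne; ++i) {
    double xi = eval(i, 0), yi = eval(i, 1), acc = 0.0;
    for (int j = 0; j < ns; ++j) {
      if (st[j] == 0.0) continue;
      double dx = xi - sx[j], dy = yi - sy[j];
      double d2 = dx * dx + dy * dy;
      if (d2 < 1e-28) continue;          // self term handled by caller
      acc += st[j] * k0_fast(k * std::sqrt(d2));
    }
    out[i] = acc / TWO_PI;
  }
  return out;
}

// Sum_j strength[j] * log(|eval_i - src_j|) / (2*pi); coincident pairs skipped.
// [[Rcpp::export]]
NumericVector cpp_log_sum(NumericMatrix eval, NumericMatrix src,
                          NumericVector strength) {
  int ne = eval.nrow(), ns = src.nrow();
  NumericVector out(ne);
  for (int i = 0; i < ne; ++i) {
    double xi = eval(i, 0), yi = eval(i, 1), acc = 0.0;
    for (int j = 0; j < ns; ++j) {
      if (strength[j] == 0.0) continue;
      double dx = xi - src(j, 0), dy = yi - src(j, 1);
      double d2 = dx * dx + dy * dy;
      if (d2 < 1e-28) continue;
      acc += strength[j] * 0.5 * std::log(d2);
    }
    out[i] = acc / TWO_PI;
  }
  return out;
}

// Sum_j strength[j] * ((eval_i - src_j) . n_i) / (2*pi*|eval_i - src_j|^2):
// normal derivative at eval_i of the sum of log-kernels at src_j.
// [[Rcpp::export]]
NumericVector cpp_gradlog_dot_n(NumericMatrix eval, NumericMatrix normals,
                                NumericMatrix src, NumericVector strength) {
  int ne = eval.nrow(), ns = src.nrow();
  NumericVector out(ne);
  for (int i = 0; i < ne; ++i) {
    double xi = eval(i, 0), yi = eval(i, 1);
    double nx = normals(i, 0), ny = normals(i, 1);
    double acc = 0.0;
    for (int j = 0; j < ns; ++j) {
      if (strength[j] == 0.0) continue;
      double dx = xi - src(j, 0), dy = yi - src(j, 1);
      double d2 = dx * dx + dy * dy;
      if (d2 < 1e-28) continue;
      acc += strength[j] * (dx * nx + dy * ny) / d2;
    }
    out[i] = acc / TWO_PI;
  }
  return out;
}

// Crossing-number point-in-polygon test (boundary points count as inside up
// to floating-point grazing).
// [[Rcpp::export]]
LogicalVector cpp_point_in_poly(NumericMatrix pts, NumericVector px,
                                NumericVector py) {
  int np = pts.nrow(), nv = px.size();
  LogicalVector out(np);
  for (int i = 0; i < np; ++i) {
    double x = pts(i, 0), y = pts(i, 1);
    bool inside = false;
    for (int j = 0, k = nv - 1; j < nv; k = j++) {
      bool cross = ((py[j] > y) != (py[k] > y)) &&
        (x < (px[k] - px[j]) * (y - py[j]) / (py[k] - py[j]) + px[j]);
      if (cross) inside = !inside;
    }
    out[i] = inside;
  }
  return out;
}

// Area and centroid of polygon INTERSECT axis-aligned box, via successive
// Sutherland-Hodgman half-plane clipping. Returns c(area, cx, cy); area 0 if
// the intersection is empty. Non-convex subjects may yield degenerate
// bridging edges, which carry zero area and do not bias the centroid.
// [[Rcpp::export]]
NumericVector cpp_clip_cell(NumericVector px, NumericVector py,
                            double xlo, double xhi, double ylo, double yhi) {
  std::vector<double> sx(px.begin(), px.end()), sy(py.begin(), py.end());
  std::vector<double> ox, oy;
  // clip planes: keep a*x + b*y <= c
  double A[4] = {-1, 1, 0, 0}, B[4] = {0, 0, -1, 1},
         C[4] = {-xlo, xhi, -ylo, yhi};
  for (int k = 0; k < 4; ++k) {
    ox.clear(); oy.clear();
    int n = sx.size();
    if (n == 0) break;
    for (int i = 0; i < n; ++i) {
      int j = (i + 1) % n;
      double di = A[k] * sx[i] + B[k] * sy[i] - C[k];
      double dj = A[k] * sx[j] + B[k] * sy[j] - C[k];
      if (di <= 0) { ox.push_back(sx[i]); oy.push_back(sy[i]); }
      if ((di < 0 && dj > 0) || (di > 0 && dj < 0)) {
        double t = di / (di - dj);
        ox.push_back(sx[i] + t * (sx[j] - sx[i]));
        oy.push_back(sy[i] + t * (sy[j] - sy[i]));
      }
    }
    sx = ox; sy = oy;
  }
  int n = sx.size();
  NumericVector out(3);
  if (n < 3) return out;
  double a2 = 0, cx = 0, cy = 0;
  for (int i = 0; i < n; ++i) {
    int j = (i + 1) % n;
    double cr = sx[i] * sy[j] - sx[j] * sy[i];
    a2 += cr;
    cx += (sx[i] + sx[j]) * cr;
    cy += (sy[i] + sy[j]) * cr;
  }
  double area = 0.5 * a2;
  out[0] = area;
  if (std::fabs(area) > 1e-300) {
    out[1] = cx / (3 * a2);
    out[2] = cy / (3 * a2);
  }
  return out;
}

namespace {
inline double orient(double ax, double ay, double bx, double by,
                     double cx, double cy) {
  return (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
}
inline bool seg_intersect(double ax, double ay, double bx, double by,
                          double cx, double cy, double dx, double dy) {
  double d1 = orient(cx, cy, dx, dy, ax, ay);
  double d2 = orient(cx, cy, dx, dy, bx, by);
  double d3 = orient(ax, ay, bx, by, cx, cy);
  double d4 = orient(ax, ay, bx, by, dx, dy);
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
    return true;
  return false;
}
} // namespace

// TRUE if the closed polygon is simple (no crossing between non-adjacent
// edges). Touching at shared endpoints of adjacent edges is allowed.
// [[Rcpp::export]]
bool cpp_poly_simple(NumericVector x, NumericVector y) {
  int n = x.size();
  for (int i = 0; i < n; ++i) {
    int i2 = (i + 1) % n;
    for (int j = i + 2; j < n; ++j) {
      int j2 = (j + 1) % n;
      if (i == j2 || i2 == j) continue;   // adjacent edges share a vertex
      if (seg_intersect(x[i], y[i], x[i2], y[i2], x[j], y[j], x[j2], y[j2]))
        return false;
    }
  }
  return true;
}
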