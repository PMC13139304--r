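#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <map>
#include <utility>

// Incremental Bowyer-Watson Delaunay triangulation of 2D points.
// Plain O(n * T) cavity search; adequate for the <= ~20k projected
// crown vertices this package feeds it.

namespace {

struct Tri {
  int a, b, c;
  double cx, cy, r2;   // circumcircle
  bool alive;
};

inline void circumcircle(const std::vector<double>& px,
                         const std::vector<double>& py,
                         Tri& t) {
  double ax = px[t.a], ay = py[t.a];
  double bx = px[t.b], by = py[t.b];
  double cx = px[t.c], cy = py[t.c];
  double d = 2.0 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by));
  if (std::fabs(d) < 1e-300) { // collinear: circle at infinity
    t.cx = t.cy = 0.0;
    t.r2 = std::numeric_limits<double>::infinity();
    return;
  }
  double a2 = ax * ax + ay * ay;
  double b2 = bx * bx + by * by;
  double c2 = cx * cx + cy * cy;
  t.cx = (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d;
  t.cy = (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d;
  double dx = ax - t.cx, dy = ay - t.cy;
  t.r2 = dx * dx + dy * dy;
}

} // namespace

// [[Rcpp::export(name = ".cpp_delaunay")]]
Rcpp::IntegerMatrix cpp_delaunay(Rcpp::NumericMatrix pts) {
  int n = pts.nrow();
  if (n < 3) Rcpp::stop("need at least 3 points for a triangulation");
  std::vector<double> px(n + 3), py(n + 3);
  double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
  for (int i = 0; i < n; ++i) {
    px[i] = pts(i, 0); py[i] = pts(i, 1);
    xmin = std::min(xmin, px[i]); xmax = std::max(xmax, px[i]);
    ymin = std::min(ymin, py[i]); ymax = std::max(ymax, py[i]);
  }
  double dx = xmax - xmin, dy = ymax - ymin;
  double dmax = std::max(dx, dy);
  if (dmax <= 0) Rcpp::stop("all points coincide");
  double midx = 0.5 * (xmin + xmax), midy = 0.5 * (ymin + ymax);
  // super-triangle well outside the data
  px[n]     = midx - 20.0 * dmax; py[n]     = midy - 10.0 * dmax;
  px[n + 1] = midx + 20.0 * dmax; py[n + 1] = midy - 10.0 * dmax;
  px[n + 2] = midx;               py[n + 2] = midy + 20.0 * dmax;

  std::vector<Tri> tris;
  {
    Tri t; t.a = n; t.b = n + 1; t.c = n + 2; t.alive = true;
    circumcircle(px, py, t);
    tris.push_back(t);
  }

  std::vector<int> bad;
  typedef std::pair<int, int> Edge;
  std::map<Edge, std::pair<int, int> > edgeCount; // undirected -> (count, oriented-first)

  for (int ip = 0; ip < n; ++ip) {
    double x = px[ip], y = py[ip];
    bad.clear();
    for (size_t it = 0; it < tris.size(); ++it) {
      if (!tris[it].alive) continue;
      double ddx = x - tris[it].cx, ddy = y - tris[it].cy;
      if (ddx * ddx + ddy * ddy <= tris[it].r2 * (1.0 + 1e-12)) bad.push_back((int)it);
    }
    if (bad.empty()) continue; // duplicate / degenerate point: skip
    edgeCount.clear();
    for (size_t k = 0; k < bad.size(); ++k) {
      const Tri& t = tris[bad[k]];
      int e[3][2] = { {t.a, t.b}, {t.b, t.c}, {t.c, t.a} };
      for (int j = 0; j < 3; ++j) {
        int u = e[j][0], v = e[j][1];
        Edge key(std::min(u, v), std::max(u, v));
        std::map<Edge, std::pair<int, int> >::iterator f = edgeCount.find(key);
        if (f == edgeCount.end()) edgeCount[key] = std::make_pair(1, u);
        else f->second.first += 1;
      }
      tris[bad[k]].alive = false;
    }
    for (std::map<Edge, std::pair<int, int> >::iterator f = edgeCount.begin();
         f != edgeCount.end(); ++f) {
      if (f->second.first != 1) continue; // interior cavity edge
      int u = f->second.second;
      int v = (f->first.first == u) ? f->first.second : f->first.first;
      Tri t; t.a = u; t.b = v; t.c = ip; t.alive = true;
      circumcircle(px, py, t);
      tris.push_back(t);
    }
  }

  int m = 0;
  for (size_t it = 0; it < tris.size(); ++it)
    if (tris[it].alive && tris[it].a < n && tris[it].b < n && tris[it].c < n) ++m;
  Rcpp::IntegerMatrix out(m, 3);
  int r = 0;
  for (size_t it = 0; it < tris.size(); ++it) {
    const Tri& t = tris[it];
    if (!t.alive || t.a >= n || t.b >= n || t.c >= n) continue;
    out(r, 0) = t.a; out(r, 1) = t.b; out(r, 2) = t.c;
    ++r;
  }
  return out; // 0-based vertex indices
}
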