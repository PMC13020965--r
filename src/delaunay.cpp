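#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <map>
#include <utility>

// Bowyer-Watson 2-D Delaunay triangulation, deterministic insertion in input
// order.  Incircle/orientation tests use long double accumulation; points
// exactly on a circumcircle are treated as outside, which keeps the
// triangulation valid (any diagonal of a cocircular quad is Delaunay) and
// deterministic on regular grids.

namespace {

struct Tri { int a, b, c; bool alive; };

inline long double orient2d(long double ax, long double ay,
                            long double bx, long double by,
                            long double cx, long double cy) {
  return (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
}

// > 0 when p lies strictly inside the circumcircle of (a, b, c) given ccw abc
inline long double incircle(long double ax, long double ay,
                            long double bx, long double by,
                            long double cx, long double cy,
                            long double px, long double py) {
  long double adx = ax - px, ady = ay - py;
  long double bdx = bx - px, bdy = by - py;
  long double cdx = cx - px, cdy = cy - py;
  long double ad = adx * adx + ady * ady;
  long double bd = bdx * bdx + bdy * bdy;
  long double cd = cdx * cdx + cdy * cdy;
  return adx * (bdy * cd - bd * cdy)
       - ady * (bdx * cd - bd * cdx)
       + ad  * (bdx * cdy - bdy * cdx);
}

} // namespace

// [[Rcpp::export(name = ".delaunay2d")]]
Rcpp::IntegerMatrix delaunay2d(Rcpp::NumericVector x, Rcpp::NumericVector y) {
  const int n = x.size();
  if (n < 3) Rcpp::stop("need at least 3 points");

  std::vector<long double> px(n + 3), py(n + 3);
  long double xmin = x[0], xmax = x[0], ymin = y[0], ymax = y[0];
  for (int i = 0; i < n; ++i) {
    px[i] = x[i]; py[i] = y[i];
    if (x[i] < xmin) xmin = x[i];
    if (x[i] > xmax) xmax = x[i];
    if (y[i] < ymin) ymin = y[i];
    if (y[i] > ymax) ymax = y[i];
  }
  long double dx = xmax - xmin, dy = ymax - ymin;
  long double dmax = (dx > dy ? dx : dy);
  if (dmax <= 0) dmax = 1;
  long double cx = (xmin + xmax) / 2, cy = (ymin + ymax) / 2;
  // super-triangle well outside the hull
  px[n]     = cx - 20 * dmax; py[n]     = cy - 10 * dmax;
  px[n + 1] = cx + 20 * dmax; py[n + 1] = cy - 10 * dmax;
  px[n + 2] = cx;             py[n + 2] = cy + 20 * dmax;

  std::vector<Tri> tris;
  tris.push_back({n, n + 1, n + 2, true});

  std::vector<int> bad;
  typedef std::pair<int, int> Edge;
  std::map<Edge, int> edgeCount;

  for (int ip = 0; ip < n; ++ip) {
    bad.clear();
    for (size_t t = 0; t < tris.size(); ++t) {
      if (!tris[t].alive) continue;
      const Tri& tr = tris[t];
      if (incircle(px[tr.a], py[tr.a], px[tr.b], py[tr.b],
                   px[tr.c], py[tr.c], px[ip], py[ip]) > 0)
        bad.push_back((int)t);
    }
    if (bad.empty()) {
      // duplicate or degenerate point configuration
      Rcpp::stop("degenerate point configuration at input point %d (duplicate point?)", ip + 1);
    }
    edgeCount.clear();
    for (int bi : bad) {
      Tri& tr = tris[bi];
      tr.alive = false;
      int e[3][2] = {{tr.a, tr.b}, {tr.b, tr.c}, {tr.c, tr.a}};
      for (int k = 0; k < 3; ++k) {
        Edge key(std::min(e[k][0], e[k][1]), std::max(e[k][0], e[k][1]));
        edgeCount[key]++;
      }
    }
    // boundary edges of the cavity appear exactly once
    for (std::map<Edge, int>::const_iterator it = edgeCount.begin();
         it != edgeCount.end(); ++it) {
      if (it->second != 1) continue;
      int a = it->first.first, b = it->first.second;
      // orient ccw
      if (orient2d(px[a], py[a], px[b], py[b], px[ip], py[ip]) < 0) std::swap(a, b);
      tris.push_back({a, b, ip, true});
    }
  }

  std::vector<int> out;
  for (size_t t = 0; t < tris.size(); ++t) {
    const Tri& tr = tris[t];
    if (!tr.alive) continue;
    if (tr.a >= n || tr.b >= n || tr.c >= n) continue; // touches super-triangle
    out.push_back(tr.a); out.push_back(tr.b); out.push_back(tr.c);
  }
  const int m = (int)out.size() / 3;
  Rcpp::IntegerMatrix res(m, 3);
  for (int t = 0; t < m; ++t) {
    res(t, 0) = out[3 * t] + 1;     // 1-based for R
    res(t, 1) = out[3 * t + 1] + 1;
    res(t, 2) = out[3 * t + 2] + 1;
  }
  return res;
}
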