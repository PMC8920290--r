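// Ripley's K over a convex polygon window with translation / isotropic
// edge corrections. The window is the convex hull of the measured cells,
// supplied as counter-clockwise vertices. Weights are exact for convex
// polygons: translation uses Sutherland-Hodgman clipping of W against its
// translate; isotropic uses the arc fraction of the circle centred at the
// first point of the pair that lies inside the polygon.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

struct Pt { double x, y; };

double polyArea(const std::vector<Pt>& p) {
  const size_t n = p.size();
  if (n < 3) return 0.0;
  double s = 0.0;
  for (size_t i = 0; i < n; ++i) {
    const Pt& a = p[i];
    const Pt& b = p[(i + 1) % n];
    s += a.x * b.y - b.x * a.y;
  }
  return 0.5 * s;  // positive for CCW
}

// Clip convex polygon `poly` by the half-plane on the left of edge a->b
// (interior side for a CCW clip polygon).
std::vector<Pt> clipHalfPlane(const std::vector<Pt>& poly, Pt a, Pt b) {
  std::vector<Pt> out;
  const size_t n = poly.size();
  if (n == 0) return out;
  out.reserve(n + 1);
  const double ex = b.x - a.x, ey = b.y - a.y;
  auto side = [&](const Pt& p) { return ex * (p.y - a.y) - ey * (p.x - a.x); };
  for (size_t i = 0; i < n; ++i) {
    const Pt& cur = poly[i];
    const Pt& nxt = poly[(i + 1) % n];
    const double sc = side(cur), sn = side(nxt);
    if (sc >= 0.0) out.push_back(cur);
    if ((sc > 0.0 && sn < 0.0) || (sc < 0.0 && sn > 0.0)) {
      const double t = sc / (sc - sn);
      out.push_back({cur.x + t * (nxt.x - cur.x), cur.y + t * (nxt.y - cur.y)});
    }
  }
  return out;
}

// |W intersect (W + v)| for convex CCW polygon W.
double shiftIntersectArea(const std::vector<Pt>& w, double vx, double vy) {
  std::vector<Pt> cur = w;
  const size_t n = w.size();
  for (size_t i = 0; i < n && !cur.empty(); ++i) {
    Pt a = {w[i].x + vx, w[i].y + vy};
    Pt b = {w[(i + 1) % n].x + vx, w[(i + 1) % n].y + vy};
    cur = clipHalfPlane(cur, a, b);
  }
  return cur.size() < 3 ? 0.0 : polyArea(cur);
}

// Fraction of the circumference of the circle centred at c with radius rad
// lying inside convex CCW polygon W. Exact: for each edge half-plane the
// excluded angles form one arc; the union of arcs is measured on [0, 2pi).
double circleInsideFraction(const std::vector<Pt>& w, Pt c, double rad) {
  const double TWO_PI = 2.0 * M_PI;
  std::vector<std::pair<double, double>> arcs;  // excluded [lo, hi] in [0, 2pi)
  const size_t n = w.size();
  for (size_t i = 0; i < n; ++i) {
    const Pt& a = w[i];
    const Pt& b = w[(i + 1) % n];
    double ex = b.x - a.x, ey = b.y - a.y;
    const double len = std::sqrt(ex * ex + ey * ey);
    if (len <= 0.0) continue;
    ex /= len; ey /= len;
    // inward normal of a CCW edge is (-ey, ex); signed distance of centre
    const double h = -ey * (c.x - a.x) + ex * (c.y - a.y);
    if (h >= rad) continue;          // circle fully inside this half-plane
    if (h <= -rad) return 0.0;       // circle fully outside
    const double half = std::acos(h / rad);           // excluded half-width
    const double mid = std::atan2(-ex, ey);           // outward normal angle
    double lo = mid - half, hi = mid + half;
    // normalise to [0, 2pi), splitting wrapped arcs
    auto norm = [&](double t) {
      t -= TWO_PI * std::floor(t / TWO_PI);
      return (t >= TWO_PI || t < 0.0) ? 0.0 : t;
    };
    lo = norm(lo); hi = norm(hi);
    if (lo <= hi) arcs.push_back({lo, hi});
    else { arcs.push_back({lo, TWO_PI}); arcs.push_back({0.0, hi}); }
  }
  if (arcs.empty()) return 1.0;
  std::sort(arcs.begin(), arcs.end());
  double excluded = 0.0, curLo = arcs[0].first, curHi = arcs[0].second;
  for (size_t i = 1; i < arcs.size(); ++i) {
    if (arcs[i].first <= curHi) curHi = std::max(curHi, arcs[i].second);
    else { excluded += curHi - curLo; curLo = arcs[i].first; curHi = arcs[i].second; }
  }
  excluded += curHi - curLo;
  double frac = 1.0 - excluded / TWO_PI;
  return frac < 0.0 ? 0.0 : frac;
}

std::vector<Pt> asPoly(const NumericVector& hx, const NumericVector& hy) {
  std::vector<Pt> w(hx.size());
  for (int i = 0; i < hx.size(); ++i) w[i] = {hx[i], hy[i]};
  return w;
}

// correction: 0 = none, 1 = translation, 2 = isotropic
double pairWeight(const std::vector<Pt>& w, double area, Pt pi_, Pt pj,
                  int correction, double cap) {
  if (correction == 0) return 1.0;
  double wt;
  if (correction == 1) {
    const double inter = shiftIntersectArea(w, pj.x - pi_.x, pj.y - pi_.y);
    wt = inter > 0.0 ? area / inter : cap;
  } else {
    const double dx = pj.x - pi_.x, dy = pj.y - pi_.y;
    const double d = std::sqrt(dx * dx + dy * dy);
    if (d <= 0.0) return 1.0;
    const double frac = circleInsideFraction(w, pi_, d);
    wt = frac > 0.0 ? 1.0 / frac : cap;
  }
  return std::min(wt, cap);
}

}  // namespace

// [[Rcpp::export(name = ".cpp_poly_area")]]
double cpp_poly_area(NumericVector hx, NumericVector hy) {
  return polyArea(asPoly(hx, hy));
}

// [[Rcpp::export(name = ".cpp_edge_weight")]]
double cpp_edge_weight(double xi, double yi, double xj, double yj,
                       NumericVector hx, NumericVector hy,
                       int correction, double cap) {
  std::vector<Pt> w = asPoly(hx, hy);
  return pairWeight(w, polyArea(w), {xi, yi}, {xj, yj}, correction, cap);
}

// Univariate K-hat on an ascending radius grid; strict indicator d < r.
// [[Rcpp::export(name = ".cpp_ripley_k")]]
NumericVector cpp_ripley_k(NumericVector px, NumericVector py,
                           NumericVector hx, NumericVector hy,
                           NumericVector r, int correction) {
  const int n = px.size(), nr = r.size();
  std::vector<Pt> w = asPoly(hx, hy);
  const double area = polyArea(w);
  const double rmax = nr ? r[nr - 1] : 0.0;
  const double cap = static_cast<double>(n);
  NumericVector acc(nr, 0.0);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      if (i == j) continue;
      const double dx = px[j] - px[i], dy = py[j] - py[i];
      const double d = std::sqrt(dx * dx + dy * dy);
      if (d >= rmax) continue;
      const double wt = pairWeight(w, area, {px[i], py[i]}, {px[j], py[j]},
                                   correction, cap);
      for (int k = nr - 1; k >= 0 && d < r[k]; --k) acc[k] += wt;
    }
  }
  const double norm = area / (static_cast<double>(n) * (n - 1.0));
  for (int k = 0; k < nr; ++k) acc[k] *= norm;
  return acc;
}

// Bivariate (cross) K-hat: anchors centre the rings (and the isotropic
// circles); strict indicator d < r.
// [[Rcpp::export(name = ".cpp_ripley_k_cross")]]
NumericVector cpp_ripley_k_cross(NumericVector ax, NumericVector ay,
                                 NumericVector bx, NumericVector by,
                                 NumericVector hx, NumericVector hy,
                                 NumericVector r, int correction) {
  const int n1 = ax.size(), n2 = bx.size(), nr = r.size();
  std::vector<Pt> w = asPoly(hx, hy);
  const double area = polyArea(w);
  const double rmax = nr ? r[nr - 1] : 0.0;
  const double cap = static_cast<double>(n1 + n2);
  NumericVector acc(nr, 0.0);
  for (int i = 0; i < n1; ++i) {
    for (int j = 0; j < n2; ++j) {
      const double dx = bx[j] - ax[i], dy = by[j] - ay[i];
      const double d = std::sqrt(dx * dx + dy * dy);
      if (d >= rmax) continue;
      const double wt = pairWeight(w, area, {ax[i], ay[i]}, {bx[j], by[j]},
                                   correction, cap);
      for (int k = nr - 1; k >= 0 && d < r[k]; --k) acc[k] += wt;
    }
  }
  const double norm = area / (static_cast<double>(n1) * n2);
  for (int k = 0; k < nr; ++k) acc[k] *= norm;
  return acc;
}
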