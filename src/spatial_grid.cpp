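// Bucket-grid neighbor queries for planar and toroidal point sets.
//
// Both routines must agree bit-for-bit with the exhaustive R path: squared
// distances are accumulated as dx*dx + dy*dy on |differences| (toroidal
// wrap via min(d, W - d)), ties on exact d2 equality resolved by the
// smaller integer id code, and a point never matches a candidate carrying
// its own id code.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Grid {
  int nx, ny;
  double x0, y0, csx, csy;
  bool torus;
  std::vector<std::vector<int> > buckets;

  static int clampi(int v, int lo, int hi) {
    return v < lo ? lo : (v > hi ? hi : v);
  }
  static int wrapi(int v, int n) {
    int m = v % n;
    return m < 0 ? m + n : m;
  }
  int rawx(double x) const { return (int)std::floor((x - x0) / csx); }
  int rawy(double y) const { return (int)std::floor((y - y0) / csy); }
  int bx(int raw) const { return torus ? wrapi(raw, nx) : clampi(raw, 0, nx - 1); }
  int by(int raw) const { return torus ? wrapi(raw, ny) : clampi(raw, 0, ny - 1); }
  const std::vector<int>& bucket(int ci, int cj) const {
    return buckets[(size_t)cj * nx + ci];
  }
};

Grid build_grid(const NumericVector& px, const NumericVector& py,
                bool torus, double Wx, double Wy, double target_cs) {
  Grid g;
  g.torus = torus;
  const int n = px.size();
  double xmin, xmax, ymin, ymax;
  if (torus) {
    xmin = 0.0; ymin = 0.0; xmax = Wx; ymax = Wy;
  } else {
    xmin = ymin = R_PosInf; xmax = ymax = R_NegInf;
    for (int i = 0; i < n; ++i) {
      if (px[i] < xmin) xmin = px[i];
      if (px[i] > xmax) xmax = px[i];
      if (py[i] < ymin) ymin = py[i];
      if (py[i] > ymax) ymax = py[i];
    }
  }
  double ext_x = xmax - xmin, ext_y = ymax - ymin;
  if (!(ext_x > 0)) ext_x = 1.0;
  if (!(ext_y > 0)) ext_y = 1.0;
  double cs = target_cs;
  if (!(cs > 0)) cs = std::sqrt(ext_x * ext_y / (double)std::max(n, 1));
  if (!(cs > 0)) cs = 1.0;
  g.nx = Grid::clampi((int)std::ceil(ext_x / cs), 1, 2048);
  g.ny = Grid::clampi((int)std::ceil(ext_y / cs), 1, 2048);
  g.x0 = xmin; g.y0 = ymin;
  g.csx = ext_x / g.nx;
  g.csy = ext_y / g.ny;
  g.buckets.assign((size_t)g.nx * g.ny, std::vector<int>());
  for (int i = 0; i < n; ++i)
    g.buckets[(size_t)g.by(g.rawy(py[i])) * g.nx + g.bx(g.rawx(px[i]))].push_back(i);
  return g;
}

inline double dist2(double ax, double ay, double bx, double by,
                    bool torus, double Wx, double Wy) {
  double dx = std::fabs(ax - bx), dy = std::fabs(ay - by);
  if (torus) {
    double wx = Wx - dx; if (wx < dx) dx = wx;
    double wy = Wy - dy; if (wy < dy) dy = wy;
  }
  return dx * dx + dy * dy;
}

} // namespace

// Directed nearest neighbor: for each query point i, the index (1-based)
// of the closest candidate point and the distance.  Candidates whose id
// code equals the query's id code are skipped; exact-distance ties go to
// the smaller candidate code.
// [[Rcpp::export(name = ".nn_grid_cpp")]]
List nn_grid_cpp(NumericVector qx, NumericVector qy, IntegerVector qcode,
                 NumericVector px, NumericVector py, IntegerVector pcode,
                 bool torus, double Wx, double Wy) {
  const int nq = qx.size(), np = px.size();
  IntegerVector idx(nq, NA_INTEGER);
  NumericVector dist(nq, NA_REAL);
  if (np == 0) return List::create(_["index"] = idx, _["distance"] = dist);

  Grid g = build_grid(px, py, torus, Wx, Wy, -1.0);
  const double cs_min = std::min(g.csx, g.csy);

  for (int i = 0; i < nq; ++i) {
    const int qi = g.rawx(qx[i]), qj = g.rawy(qy[i]);
    double best_d2 = R_PosInf;
    int best_j = -1, best_code = 0;

    // all grid cells are within this Chebyshev radius of the query cell
    int m_done;
    if (g.torus) {
      m_done = std::max(g.nx, g.ny); // full-scan switch handles coverage
    } else {
      int mx = std::max(std::abs(qi - 0), std::abs(g.nx - 1 - qi));
      int my = std::max(std::abs(qj - 0), std::abs(g.ny - 1 - qj));
      m_done = std::max(mx, my);
    }

    for (int m = 0; ; ++m) {
      bool scanned_all = false;
      if (g.torus && (2 * m + 1 >= std::min(g.nx, g.ny))) {
        // wrap-around shortcuts possible: scan every bucket once
        for (int cj = 0; cj < g.ny; ++cj)
          for (int ci = 0; ci < g.nx; ++ci) {
            const std::vector<int>& b = g.bucket(ci, cj);
            for (size_t k = 0; k < b.size(); ++k) {
              const int j = b[k];
              if (pcode[j] == qcode[i]) continue;
              double d2 = dist2(qx[i], qy[i], px[j], py[j], g.torus, Wx, Wy);
              if (d2 < best_d2 || (d2 == best_d2 && pcode[j] < best_code)) {
                best_d2 = d2; best_j = j; best_code = pcode[j];
              }
            }
          }
        scanned_all = true;
      } else {
        // Chebyshev ring m around (qi, qj)
        for (int dj = -m; dj <= m; ++dj) {
          const int rj = qj + dj;
          if (!g.torus && (rj < 0 || rj >= g.ny)) continue;
          const int cj = g.torus ? Grid::wrapi(rj, g.ny) : rj;
          const bool edge_row = (std::abs(dj) == m);
          const int step = edge_row ? 1 : 2 * m;
          for (int di = -m; di <= m; di += (m == 0 ? 1 : step)) {
            const int ri = qi + di;
            if (!g.torus && (ri < 0 || ri >= g.nx)) continue;
            const int ci = g.torus ? Grid::wrapi(ri, g.nx) : ri;
            const std::vector<int>& b = g.bucket(ci, cj);
            for (size_t k = 0; k < b.size(); ++k) {
              const int j = b[k];
              if (pcode[j] == qcode[i]) continue;
              double d2 = dist2(qx[i], qy[i], px[j], py[j], g.torus, Wx, Wy);
              if (d2 < best_d2 || (d2 == best_d2 && pcode[j] < best_code)) {
                best_d2 = d2; best_j = j; best_code = pcode[j];
              }
            }
            if (m == 0) break;
          }
        }
      }
      // points in unscanned cells (ring >= m+1) lie at distance >= m*cs_min;
      // strict inequality rules out both closer points and exact ties
      const double bound = (double)m * cs_min;
      if (scanned_all) break;
      if (best_j >= 0 && best_d2 < bound * bound) break;
      if (m >= m_done && best_j >= 0) break;
      if (m >= m_done && !g.torus) break; // grid exhausted, nothing found
    }

    if (best_j >= 0) {
      idx[i] = best_j + 1;
      dist[i] = std::sqrt(best_d2);
    }
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}

// Fixed-radius counts: for each center, the number of candidate points with
// d2 <= r^2 (inclusive) or d2 < r^2 (exclusive), skipping same-id codes.
// [[Rcpp::export(name = ".count_within_cpp")]]
IntegerVector count_within_cpp(NumericVector cx, NumericVector cy, IntegerVector ccode,
                               NumericVector px, NumericVector py, IntegerVector pcode,
                               double r, bool inclusive,
                               bool torus, double Wx, double Wy) {
  const int nc = cx.size(), np = px.size();
  IntegerVector out(nc, 0);
  if (np == 0) return out;

  Grid g = build_grid(px, py, torus, Wx, Wy, r > 0 ? r : -1.0);
  const double r2 = r * r;
  const int mx = (int)std::ceil(r / g.csx) + 1;
  const int my = (int)std::ceil(r / g.csy) + 1;

  for (int i = 0; i < nc; ++i) {
    const int qi = g.rawx(cx[i]), qj = g.rawy(cy[i]);
    int cnt = 0;
    int jlo = qj - my, jhi = qj + my, ilo = qi - mx, ihi = qi + mx;
    const bool full_x = g.torus && (ihi - ilo + 1 >= g.nx);
    const bool full_y = g.torus && (jhi - jlo + 1 >= g.ny);
    if (full_x) { ilo = 0; ihi = g.nx - 1; }
    if (full_y) { jlo = 0; jhi = g.ny - 1; }
    if (!g.torus) {
      ilo = Grid::clampi(ilo, 0, g.nx - 1); ihi = Grid::clampi(ihi, 0, g.nx - 1);
      jlo = Grid::clampi(jlo, 0, g.ny - 1); jhi = Grid::clampi(jhi, 0, g.ny - 1);
    }
    for (int rj = jlo; rj <= jhi; ++rj) {
      const int cj = g.torus && !full_y ? Grid::wrapi(rj, g.ny) : rj;
      for (int ri = ilo; ri <= ihi; ++ri) {
        const int ci = g.torus && !full_x ? Grid::wrapi(ri, g.nx) : ri;
        const std::vector<int>& b = g.bucket(ci, cj);
        for (size_t k = 0; k < b.size(); ++k) {
          const int j = b[k];
          if (pcode[j] == ccode[i]) continue;
          double d2 = dist2(cx[i], cy[i], px[j], py[j], g.torus, Wx, Wy);
          if (inclusive ? (d2 <= r2) : (d2 < r2)) ++cnt;
        }
      }
    }
    out[i] = cnt;
  }
  return out;
}
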