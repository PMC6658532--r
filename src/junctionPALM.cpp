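#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <queue>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Voronoi tessellation clipped to a rectangle.
//
// Each cell is obtained by Sutherland-Hodgman clipping of the bounding
// rectangle against the perpendicular bisectors of the seed and its
// neighbours, visited in order of increasing distance.  Once the next
// candidate is more than twice as far as the furthest current cell vertex it
// can no longer cut the cell and the scan stops, which keeps the cost close
// to O(n k log n) for k effective neighbours.
// ---------------------------------------------------------------------------

struct Poly {
  std::vector<double> x, y;
};

static inline double polyArea(const Poly &p) {
  const int n = p.x.size();
  double a = 0.0;
  for (int i = 0, j = n - 1; i < n; j = i++)
    a += (p.x[j] + p.x[i]) * (p.y[j] - p.y[i]);
  return std::fabs(a) * 0.5;
}

// clip polygon to half-plane {q : (q - m) . d <= 0}; returns true if cut
static bool clipHalfPlane(Poly &p, double mx, double my, double dx, double dy) {
  const int n = p.x.size();
  if (n == 0) return false;
  std::vector<double> f(n);
  bool anyOut = false, anyIn = false;
  for (int i = 0; i < n; ++i) {
    f[i] = (p.x[i] - mx) * dx + (p.y[i] - my) * dy;
    if (f[i] > 0) anyOut = true; else anyIn = true;
  }
  if (!anyOut) return false;
  Poly out;
  out.x.reserve(n + 2); out.y.reserve(n + 2);
  for (int i = 0, j = n - 1; i < n; j = i++) {
    const bool inJ = f[j] <= 0, inI = f[i] <= 0;
    if (inJ) { out.x.push_back(p.x[j]); out.y.push_back(p.y[j]); }
    if (inJ != inI) {
      const double t = f[j] / (f[j] - f[i]);
      out.x.push_back(p.x[j] + t * (p.x[i] - p.x[j]));
      out.y.push_back(p.y[j] + t * (p.y[i] - p.y[j]));
    }
  }
  p = out;
  (void)anyIn;
  return true;
}

// [[Rcpp::export]]
List voronoi_cells_cpp(NumericVector x, NumericVector y,
                       double x0, double y0, double x1, double y1) {
  const int n = x.size();
  NumericVector areas(n);
  List neighbours(n);
  std::vector<double> d2(n);
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      const double dx = x[j] - x[i], dy = y[j] - y[i];
      d2[j] = dx * dx + dy * dy;
    }
    std::iota(ord.begin(), ord.end(), 0);
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return d2[a] < d2[b]; });
    Poly cell;
    cell.x = {x0, x1, x1, x0};
    cell.y = {y0, y0, y1, y1};
    std::vector<int> nb;
    for (int k = 0; k < n; ++k) {
      const int j = ord[k];
      if (j == i) continue;
      double maxv = 0.0;
      for (size_t v = 0; v < cell.x.size(); ++v) {
        const double dx = cell.x[v] - x[i], dy = cell.y[v] - y[i];
        const double dd = dx * dx + dy * dy;
        if (dd > maxv) maxv = dd;
      }
      if (d2[j] > 4.0 * maxv) break;
      const double mx = 0.5 * (x[i] + x[j]), my = 0.5 * (y[i] + y[j]);
      if (clipHalfPlane(cell, mx, my, x[j] - x[i], y[j] - y[i]))
        nb.push_back(j + 1);
    }
    areas[i] = polyArea(cell);
    neighbours[i] = IntegerVector(nb.begin(), nb.end());
  }
  return List::create(_["areas"] = areas, _["neighbours"] = neighbours);
}

// ---------------------------------------------------------------------------
// Nearest-seed index for every pixel centre of a raster (bucket-grid search).
// Pixel (i, j), 1-based in R, has centre (x0 + (i - 0.5) p, y0 + (j - 0.5) p).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix nearest_seed_map_cpp(NumericVector sx, NumericVector sy,
                                   double x0, double y0, double pixel,
                                   int nx, int ny) {
  const int n = sx.size();
  IntegerMatrix out(nx, ny);
  if (n == 0) return out;
  // bucket grid over the raster extent
  const double w = nx * pixel, h = ny * pixel;
  int ngx = std::max(1, (int)std::floor(std::sqrt((double)n * w / std::max(h, 1e-9))));
  int ngy = std::max(1, (int)(n / std::max(ngx, 1)));
  ngx = std::min(ngx, 256); ngy = std::min(ngy, 256);
  const double bx = w / ngx, by = h / ngy;
  std::vector<std::vector<int> > bucket(ngx * ngy);
  for (int s = 0; s < n; ++s) {
    int gx = (int)std::floor((sx[s] - x0) / bx);
    int gy = (int)std::floor((sy[s] - y0) / by);
    gx = std::min(std::max(gx, 0), ngx - 1);
    gy = std::min(std::max(gy, 0), ngy - 1);
    bucket[gx + ngx * gy].push_back(s);
  }
  const double bmin = std::min(bx, by);
  for (int j = 0; j < ny; ++j) {
    const double py = y0 + (j + 0.5) * pixel;
    int gy0 = std::min(std::max((int)std::floor((py - y0) / by), 0), ngy - 1);
    for (int i = 0; i < nx; ++i) {
      const double px = x0 + (i + 0.5) * pixel;
      int gx0 = std::min(std::max((int)std::floor((px - x0) / bx), 0), ngx - 1);
      double best = R_PosInf; int bestIdx = -1;
      for (int ring = 0; ring < std::max(ngx, ngy); ++ring) {
        if (bestIdx >= 0 && (double)(ring - 1) * bmin > std::sqrt(best)) break;
        bool any = false;
        for (int gy = gy0 - ring; gy <= gy0 + ring; ++gy) {
          if (gy < 0 || gy >= ngy) continue;
          for (int gx = gx0 - ring; gx <= gx0 + ring; ++gx) {
            if (gx < 0 || gx >= ngx) continue;
            if (std::max(std::abs(gx - gx0), std::abs(gy - gy0)) != ring) continue;
            any = true;
            const std::vector<int> &b = bucket[gx + ngx * gy];
            for (size_t t = 0; t < b.size(); ++t) {
              const int s = b[t];
              const double dx = sx[s] - px, dy = sy[s] - py;
              const double dd = dx * dx + dy * dy;
              if (dd < best) { best = dd; bestIdx = s; }
            }
          }
        }
        if (!any && bestIdx >= 0) break;
      }
      out(i, j) = bestIdx + 1;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Minimum-cost linear assignment (Hungarian algorithm with potentials).
// cost: n x m with n <= m; returns for each row the 1-based assigned column.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector hungarian_lsap_cpp(NumericMatrix cost) {
  const int n = cost.nrow(), m = cost.ncol();
  if (n > m) stop("cost matrix must have nrow <= ncol");
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> u(n + 1, 0.0), v(m + 1, 0.0);
  std::vector<int> p(m + 1, 0), way(m + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(m + 1, INF);
    std::vector<char> used(m + 1, 0);
    do {
      used[j0] = 1;
      const int i0 = p[j0];
      int j1 = -1;
      double delta = INF;
      for (int j = 1; j <= m; ++j) if (!used[j]) {
        const double cur = cost(i0 - 1, j - 1) - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= m; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do { const int j1 = way[j0]; p[j0] = p[j1]; j0 = j1; } while (j0);
  }
  IntegerVector ans(n);
  for (int j = 1; j <= m; ++j) if (p[j] > 0) ans[p[j] - 1] = j;
  return ans;
}

// ---------------------------------------------------------------------------
// 8-connected component labelling of a binary matrix.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix label8_cpp(IntegerMatrix m) {
  const int nx = m.nrow(), ny = m.ncol();
  IntegerMatrix lab(nx, ny);
  int next = 0;
  std::vector<std::pair<int, int> > stack;
  for (int j = 0; j < ny; ++j) for (int i = 0; i < nx; ++i) {
    if (m(i, j) == 0 || lab(i, j) != 0) continue;
    ++next;
    stack.clear();
    stack.push_back(std::make_pair(i, j));
    lab(i, j) = next;
    while (!stack.empty()) {
      const std::pair<int, int> c = stack.back();
      stack.pop_back();
      for (int dj = -1; dj <= 1; ++dj) for (int di = -1; di <= 1; ++di) {
        if (di == 0 && dj == 0) continue;
        const int ii = c.first + di, jj = c.second + dj;
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny) continue;
        if (m(ii, jj) != 0 && lab(ii, jj) == 0) {
          lab(ii, jj) = next;
          stack.push_back(std::make_pair(ii, jj));
        }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Count, for each point, the other points within `radius` (bucket grid).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector count_neighbours_cpp(NumericVector x, NumericVector y,
                                   double radius) {
  const int n = x.size();
  IntegerVector out(n);
  if (n == 0) return out;
  double xmin = x[0], ymin = y[0], xmax = x[0], ymax = y[0];
  for (int i = 1; i < n; ++i) {
    xmin = std::min(xmin, x[i]); xmax = std::max(xmax, x[i]);
    ymin = std::min(ymin, y[i]); ymax = std::max(ymax, y[i]);
  }
  const double cell = std::max(radius, 1e-9);
  const int ngx = std::max(1, (int)std::floor((xmax - xmin) / cell) + 1);
  const int ngy = std::max(1, (int)std::floor((ymax - ymin) / cell) + 1);
  std::vector<std::vector<int> > bucket((size_t)ngx * ngy);
  std::vector<int> gx(n), gy(n);
  for (int i = 0; i < n; ++i) {
    gx[i] = std::min((int)std::floor((x[i] - xmin) / cell), ngx - 1);
    gy[i] = std::min((int)std::floor((y[i] - ymin) / cell), ngy - 1);
    bucket[gx[i] + (size_t)ngx * gy[i]].push_back(i);
  }
  const double r2 = radius * radius;
  for (int i = 0; i < n; ++i) {
    int cnt = 0;
    for (int dj = -1; dj <= 1; ++dj) for (int di = -1; di <= 1; ++di) {
      const int ii = gx[i] + di, jj = gy[i] + dj;
      if (ii < 0 || ii >= ngx || jj < 0 || jj >= ngy) continue;
      const std::vector<int> &b = bucket[ii + (size_t)ngx * jj];
      for (size_t t = 0; t < b.size(); ++t) {
        const int j = b[t];
        if (j == i) continue;
        const double dx = x[j] - x[i], dy = y[j] - y[i];
        if (dx * dx + dy * dy <= r2) ++cnt;
      }
    }
    out[i] = cnt;
  }
  return out;
}
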