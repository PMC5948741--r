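// Geometry kernels: grid-hashed k-nearest-neighbour queries, point-to-mesh
// distances, local-plane residuals and 4-connected component labelling.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <queue>
#include <cmath>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

namespace {

struct GridHash {
  double cell;
  double ox, oy, oz;
  std::unordered_map<int64_t, std::vector<int>> cells;

  static int64_t key(int ix, int iy, int iz) {
    return (static_cast<int64_t>(ix) & 0x1FFFFF) |
           ((static_cast<int64_t>(iy) & 0x1FFFFF) << 21) |
           ((static_cast<int64_t>(iz) & 0x1FFFFF) << 42);
  }

  void build(const NumericMatrix& pts, double cell_size) {
    cell = cell_size;
    ox = oy = oz = 0.0;
    int n = pts.nrow();
    if (n > 0) {
      ox = pts(0, 0); oy = pts(0, 1); oz = pts(0, 2);
      for (int i = 0; i < n; ++i) {
        ox = std::min(ox, pts(i, 0));
        oy = std::min(oy, pts(i, 1));
        oz = std::min(oz, pts(i, 2));
      }
    }
    cells.reserve(static_cast<size_t>(n));
    for (int i = 0; i < n; ++i) {
      int ix = static_cast<int>(std::floor((pts(i, 0) - ox) / cell));
      int iy = static_cast<int>(std::floor((pts(i, 1) - oy) / cell));
      int iz = static_cast<int>(std::floor((pts(i, 2) - oz) / cell));
      cells[key(ix, iy, iz)].push_back(i);
    }
  }
};

inline double sqdist(const NumericMatrix& p, int i, int j) {
  double dx = p(i, 0) - p(j, 0);
  double dy = p(i, 1) - p(j, 1);
  double dz = p(i, 2) - p(j, 2);
  return dx * dx + dy * dy + dz * dz;
}

// Exact k nearest neighbours of point i (excluding i), via expanding shells.
void knn_of_point(const NumericMatrix& pts, const GridHash& grid, int i, int k,
                  std::vector<int>& out_idx, std::vector<double>& out_d2) {
  int cx = static_cast<int>(std::floor((pts(i, 0) - grid.ox) / grid.cell));
  int cy = static_cast<int>(std::floor((pts(i, 1) - grid.oy) / grid.cell));
  int cz = static_cast<int>(std::floor((pts(i, 2) - grid.oz) / grid.cell));
  // max-heap of (d2, idx) keeping the k best
  std::priority_queue<std::pair<double, int>> heap;
  for (int ring = 0; ; ++ring) {
    // once we hold k candidates, stop when the closed shell at distance
    // (ring-1)*cell already bounds the kth distance
    if (static_cast<int>(heap.size()) == k && ring > 1) {
      double bound = (ring - 1) * grid.cell;
      if (heap.top().first <= bound * bound) break;
    }
    bool any_cell = false;
    auto visit = [&](int dx, int dy, int dz) {
      auto it = grid.cells.find(GridHash::key(cx + dx, cy + dy, cz + dz));
      if (it == grid.cells.end()) return;
      any_cell = true;
      for (int j : it->second) {
        if (j == i) continue;
        double d2 = sqdist(pts, i, j);
        if (static_cast<int>(heap.size()) < k) {
          heap.emplace(d2, j);
        } else if (d2 < heap.top().first) {
          heap.pop();
          heap.emplace(d2, j);
        }
      }
    };
    if (ring == 0) {
      visit(0, 0, 0);
    } else {
      for (int dx = -ring; dx <= ring; ++dx)
        for (int dy = -ring; dy <= ring; ++dy) {
          visit(dx, dy, -ring);
          visit(dx, dy, ring);
        }
      for (int dx = -ring; dx <= ring; ++dx)
        for (int dz = -ring + 1; dz <= ring - 1; ++dz) {
          visit(dx, -ring, dz);
          visit(dx, ring, dz);
        }
      for (int dy = -ring + 1; dy <= ring - 1; ++dy)
        for (int dz = -ring + 1; dz <= ring - 1; ++dz) {
          visit(-ring, dy, dz);
          visit(ring, dy, dz);
        }
    }
    // safety: if the shells have grown past the whole grid, stop
    if (!any_cell && ring > 0) {
      double extent = 3.0 * grid.cell * std::cbrt((double)pts.nrow() + 1.0) +
                      1.0;
      if (ring * grid.cell > extent && static_cast<int>(heap.size()) >= k)
        break;
      if (ring > 4096) break;
    }
  }
  int m = static_cast<int>(heap.size());
  out_idx.assign(m, -1);
  out_d2.assign(m, 0.0);
  for (int j = m - 1; j >= 0; --j) {
    out_idx[j] = heap.top().second;
    out_d2[j] = heap.top().first;
    heap.pop();
  }
}

double pick_cell_size(const NumericMatrix& pts, int k) {
  int n = pts.nrow();
  // brute-force kth-NN distance on a deterministic subsample
  int m = std::min(n, 64);
  double acc = 0.0;
  int used = 0;
  for (int s = 0; s < m; ++s) {
    int i = static_cast<int>((static_cast<int64_t>(s) * n) / m);
    std::vector<double> d2(n);
    for (int j = 0; j < n; ++j) d2[j] = sqdist(pts, i, j);
    std::nth_element(d2.begin(), d2.begin() + std::min(k, n - 1), d2.end());
    double dk = std::sqrt(d2[std::min(k, n - 1)]);
    if (dk > 0) { acc += dk; ++used; }
  }
  double cell = used > 0 ? acc / used : 1.0;
  if (cell <= 0 || !std::isfinite(cell)) cell = 1.0;
  return cell;
}

}  // namespace

// [[Rcpp::export]]
List cpp_knn(NumericMatrix pts, int k) {
  int n = pts.nrow();
  if (k < 1 || k >= n) stop("k must satisfy 1 <= k < n");
  GridHash grid;
  grid.build(pts, pick_cell_size(pts, k));
  NumericVector mean_dist(n);
  IntegerMatrix idx(n, k);
  std::vector<int> nb;
  std::vector<double> d2;
  for (int i = 0; i < n; ++i) {
    knn_of_point(pts, grid, i, k, nb, d2);
    double acc = 0.0;
    for (int j = 0; j < k; ++j) {
      idx(i, j) = nb[j] + 1;  // 1-based for R
      acc += std::sqrt(d2[j]);
    }
    mean_dist[i] = acc / k;
  }
  return List::create(_["mean_dist"] = mean_dist, _["indices"] = idx);
}

// Distance from each point to the total-least-squares plane of its k nearest
// neighbours (the point itself excluded). Plane from the smallest eigenvector
// of the neighbour covariance (Jacobi eigen-solver on the 3x3 matrix).
static void smallest_evec3(double c[3][3], double v[3]) {
  double a[3][3];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) a[i][j] = c[i][j];
  double q[3][3] = {{1, 0, 0}, {0, 1, 0}, {0, 0, 1}};
  for (int sweep = 0; sweep < 32; ++sweep) {
    double off = std::abs(a[0][1]) + std::abs(a[0][2]) + std::abs(a[1][2]);
    if (off < 1e-15) break;
    for (int p = 0; p < 2; ++p) {
      for (int r = p + 1; r < 3; ++r) {
        if (std::abs(a[p][r]) < 1e-18) continue;
        double theta = (a[r][r] - a[p][p]) / (2.0 * a[p][r]);
        double t = (theta >= 0 ? 1.0 : -1.0) /
                   (std::abs(theta) + std::sqrt(theta * theta + 1.0));
        double cth = 1.0 / std::sqrt(t * t + 1.0);
        double sth = t * cth;
        for (int i = 0; i < 3; ++i) {
          double aip = a[i][p], air = a[i][r];
          a[i][p] = cth * aip - sth * air;
          a[i][r] = sth * aip + cth * air;
        }
        for (int j = 0; j < 3; ++j) {
          double apj = a[p][j], arj = a[r][j];
          a[p][j] = cth * apj - sth * arj;
          a[r][j] = sth * apj + cth * arj;
        }
        for (int i = 0; i < 3; ++i) {
          double qip = q[i][p], qir = q[i][r];
          q[i][p] = cth * qip - sth * qir;
          q[i][r] = sth * qip + cth * qir;
        }
      }
    }
  }
  int best = 0;
  if (a[1][1] < a[best][best]) best = 1;
  if (a[2][2] < a[best][best]) best = 2;
  for (int i = 0; i < 3; ++i) v[i] = q[i][best];
}

// [[Rcpp::export]]
NumericVector cpp_local_plane_dist(NumericMatrix pts, int k) {
  int n = pts.nrow();
  if (k < 3 || k >= n) stop("k must satisfy 3 <= k < n");
  GridHash grid;
  grid.build(pts, pick_cell_size(pts, k));
  NumericVector out(n);
  std::vector<int> nb;
  std::vector<double> d2;
  for (int i = 0; i < n; ++i) {
    knn_of_point(pts, grid, i, k, nb, d2);
    double mx = 0, my = 0, mz = 0;
    for (int j : nb) { mx += pts(j, 0); my += pts(j, 1); mz += pts(j, 2); }
    mx /= k; my /= k; mz /= k;
    double c[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
    for (int j : nb) {
      double dx = pts(j, 0) - mx, dy = pts(j, 1) - my, dz = pts(j, 2) - mz;
      c[0][0] += dx * dx; c[0][1] += dx * dy; c[0][2] += dx * dz;
      c[1][1] += dy * dy; c[1][2] += dy * dz; c[2][2] += dz * dz;
    }
    c[1][0] = c[0][1]; c[2][0] = c[0][2]; c[2][1] = c[1][2];
    double nv[3];
    smallest_evec3(c, nv);
    double norm = std::sqrt(nv[0] * nv[0] + nv[1] * nv[1] + nv[2] * nv[2]);
    if (norm < 1e-300) { out[i] = 0.0; continue; }
    out[i] = std::abs(nv[0] * (pts(i, 0) - mx) + nv[1] * (pts(i, 1) - my) +
                      nv[2] * (pts(i, 2) - mz)) / norm;
  }
  return out;
}

// Unsigned distance from a point to a triangle (Ericson, Real-Time
// Collision Detection, closest-point-on-triangle).
static double point_tri_d2(const double p[3], const double a[3],
                           const double b[3], const double c[3]) {
  double ab[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  double ac[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
  double ap[3] = {p[0] - a[0], p[1] - a[1], p[2] - a[2]};
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  auto d2out = [&](double qx, double qy, double qz) {
    double dx = p[0] - qx, dy = p[1] - qy, dz = p[2] - qz;
    return dx * dx + dy * dy + dz * dz;
  };
  if (d1 <= 0.0 && d2 <= 0.0) return d2out(a[0], a[1], a[2]);
  double bp[3] = {p[0] - b[0], p[1] - b[1], p[2] - b[2]};
  double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0.0 && d4 <= d3) return d2out(b[0], b[1], b[2]);
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    return d2out(a[0] + v * ab[0], a[1] + v * ab[1], a[2] + v * ab[2]);
  }
  double cp[3] = {p[0] - c[0], p[1] - c[1], p[2] - c[2]};
  double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
  double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
  if (d6 >= 0.0 && d5 <= d6) return d2out(c[0], c[1], c[2]);
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    return d2out(a[0] + w * ac[0], a[1] + w * ac[1], a[2] + w * ac[2]);
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return d2out(b[0] + w * (c[0] - b[0]), b[1] + w * (c[1] - b[1]),
                 b[2] + w * (c[2] - b[2]));
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  return d2out(a[0] + ab[0] * v + ac[0] * w, a[1] + ab[1] * v + ac[1] * w,
               a[2] + ab[2] * v + ac[2] * w);
}

// [[Rcpp::export]]
NumericVector cpp_point_mesh_dist(NumericMatrix pts, NumericMatrix verts,
                                  IntegerMatrix faces) {
  int n = pts.nrow(), m = faces.nrow();
  if (m == 0) stop("reference mesh has no faces");
  NumericVector out(n);
  std::vector<double> va(3 * m), vb(3 * m), vc(3 * m);
  for (int f = 0; f < m; ++f) {
    int ia = faces(f, 0) - 1, ib = faces(f, 1) - 1, ic = faces(f, 2) - 1;
    for (int d = 0; d < 3; ++d) {
      va[3 * f + d] = verts(ia, d);
      vb[3 * f + d] = verts(ib, d);
      vc[3 * f + d] = verts(ic, d);
    }
  }
  for (int i = 0; i < n; ++i) {
    double p[3] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    double best = R_PosInf;
    for (int f = 0; f < m; ++f) {
      double d2 = point_tri_d2(p, &va[3 * f], &vb[3 * f], &vc[3 * f]);
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// 4-connected labelling of a logical matrix (column-major, as stored by R).
// Labels are assigned in raster order of each component's first pixel
// scanning rows within columns, matching R's column-major order.
// [[Rcpp::export]]
IntegerMatrix cpp_label4(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  int next = 0;
  std::vector<std::pair<int, int>> stack;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      stack.clear();
      stack.emplace_back(i, j);
      lab(i, j) = next;
      while (!stack.empty()) {
        auto [r, c] = stack.back();
        stack.pop_back();
        const int dr[4] = {-1, 1, 0, 0};
        const int dc[4] = {0, 0, -1, 1};
        for (int t = 0; t < 4; ++t) {
          int rr = r + dr[t], cc = c + dc[t];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (mask(rr, cc) && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            stack.emplace_back(rr, cc);
          }
        }
      }
    }
  }
  return lab;
}
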