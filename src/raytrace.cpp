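// Uniform-grid accelerated ray-sphere tracing.
//
// The grid covers the bounding box of the sphere set only; rays are clipped
// to that box before traversal (vacuum outside contributes nothing).
// Conventions (shared with the pure-R brute-force oracle):
//   * a grazing ray (discriminant <= 0) is a miss,
//   * spheres entirely behind the origin (t_exit <= 0) are misses,
//   * entry distances are clamped to 0 for rays starting inside a sphere,
//   * hits are sorted by entry distance.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

struct SphereGrid {
  std::vector<double> cx, cy, cz, rad;
  double x0, y0, z0, x1, y1, z1;
  double cell;
  int nx, ny, nz;
  std::vector<std::vector<int> > cells;  // 0-based sphere ids per cell
  std::vector<int> stamp;                // candidate de-duplication scratch
  int gen;

  inline int cell_index(int ix, int iy, int iz) const {
    return ix + nx * (iy + ny * iz);
  }
};

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// [[Rcpp::export]]
SEXP cpp_build_grid(NumericMatrix centers, NumericVector radii,
                    double cell_size) {
  const int n = centers.nrow();
  if (n < 1) stop("grid requires at least one sphere");
  if (cell_size <= 0) stop("cell_size must be > 0");

  SphereGrid* g = new SphereGrid();
  g->gen = 0;
  g->cell = cell_size;
  g->cx.resize(n); g->cy.resize(n); g->cz.resize(n); g->rad.resize(n);

  double x0 = R_PosInf, y0 = R_PosInf, z0 = R_PosInf;
  double x1 = R_NegInf, y1 = R_NegInf, z1 = R_NegInf;
  for (int i = 0; i < n; ++i) {
    g->cx[i] = centers(i, 0);
    g->cy[i] = centers(i, 1);
    g->cz[i] = centers(i, 2);
    g->rad[i] = radii[i];
    x0 = std::min(x0, g->cx[i] - radii[i]);
    y0 = std::min(y0, g->cy[i] - radii[i]);
    z0 = std::min(z0, g->cz[i] - radii[i]);
    x1 = std::max(x1, g->cx[i] + radii[i]);
    y1 = std::max(y1, g->cy[i] + radii[i]);
    z1 = std::max(z1, g->cz[i] + radii[i]);
  }
  const double pad = 1e-9;
  g->x0 = x0 - pad; g->y0 = y0 - pad; g->z0 = z0 - pad;
  g->x1 = x1 + pad; g->y1 = y1 + pad; g->z1 = z1 + pad;
  g->nx = std::max(1, (int)std::ceil((g->x1 - g->x0) / cell_size));
  g->ny = std::max(1, (int)std::ceil((g->y1 - g->y0) / cell_size));
  g->nz = std::max(1, (int)std::ceil((g->z1 - g->z0) / cell_size));

  g->cells.resize((size_t)g->nx * g->ny * g->nz);
  g->stamp.assign(n, -1);

  for (int i = 0; i < n; ++i) {
    int ix0 = clampi((int)std::floor((g->cx[i] - g->rad[i] - g->x0) / cell_size), 0, g->nx - 1);
    int ix1 = clampi((int)std::floor((g->cx[i] + g->rad[i] - g->x0) / cell_size), 0, g->nx - 1);
    int iy0 = clampi((int)std::floor((g->cy[i] - g->rad[i] - g->y0) / cell_size), 0, g->ny - 1);
    int iy1 = clampi((int)std::floor((g->cy[i] + g->rad[i] - g->y0) / cell_size), 0, g->ny - 1);
    int iz0 = clampi((int)std::floor((g->cz[i] - g->rad[i] - g->z0) / cell_size), 0, g->nz - 1);
    int iz1 = clampi((int)std::floor((g->cz[i] + g->rad[i] - g->z0) / cell_size), 0, g->nz - 1);
    for (int iz = iz0; iz <= iz1; ++iz)
      for (int iy = iy0; iy <= iy1; ++iy)
        for (int ix = ix0; ix <= ix1; ++ix)
          g->cells[g->cell_index(ix, iy, iz)].push_back(i);
  }

  XPtr<SphereGrid> ptr(g, true);
  return ptr;
}

// [[Rcpp::export]]
bool cpp_grid_valid(SEXP gridptr) {
  if (TYPEOF(gridptr) != EXTPTRSXP) return false;
  return R_ExternalPtrAddr(gridptr) != NULL;
}

// Clip a ray to an axis-aligned box; returns false when there is no overlap
// with [t_lo, t_hi].
static bool clip_ray(double o, double d, double lo, double hi,
                     double& t_lo, double& t_hi) {
  if (std::fabs(d) < 1e-300) return o >= lo && o <= hi;
  double ta = (lo - o) / d, tb = (hi - o) / d;
  if (ta > tb) std::swap(ta, tb);
  t_lo = std::max(t_lo, ta);
  t_hi = std::min(t_hi, tb);
  return t_lo <= t_hi;
}

// [[Rcpp::export]]
NumericMatrix cpp_ray_trace(SEXP gridptr, NumericVector origin,
                            NumericVector direction, double tmax) {
  XPtr<SphereGrid> g(gridptr);
  if (!g) stop("invalid spatial index pointer");
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const double dx = direction[0], dy = direction[1], dz = direction[2];

  double t_lo = 0.0, t_hi = tmax;
  bool inside =
      clip_ray(ox, dx, g->x0, g->x1, t_lo, t_hi) &&
      clip_ray(oy, dy, g->y0, g->y1, t_lo, t_hi) &&
      clip_ray(oz, dz, g->z0, g->z1, t_lo, t_hi);
  if (!inside || t_hi <= 0) return NumericMatrix(0, 3);
  t_lo = std::max(t_lo, 0.0);

  // 3D-DDA traversal to gather candidate spheres.
  std::vector<int> cand;
  g->gen += 1;
  const int gen = g->gen;

  const double eps = 1e-9 * std::max(1.0, t_hi - t_lo);
  double px = ox + (t_lo + eps) * dx;
  double py = oy + (t_lo + eps) * dy;
  double pz = oz + (t_lo + eps) * dz;
  int ix = clampi((int)std::floor((px - g->x0) / g->cell), 0, g->nx - 1);
  int iy = clampi((int)std::floor((py - g->y0) / g->cell), 0, g->ny - 1);
  int iz = clampi((int)std::floor((pz - g->z0) / g->cell), 0, g->nz - 1);

  const int sx = dx > 0 ? 1 : -1, sy = dy > 0 ? 1 : -1, sz = dz > 0 ? 1 : -1;
  const double inf = R_PosInf;
  double tmx, tmy, tmz, tdx, tdy, tdz;
  if (std::fabs(dx) > 1e-300) {
    double bx = g->x0 + (ix + (sx > 0 ? 1 : 0)) * g->cell;
    tmx = (bx - ox) / dx;
    tdx = g->cell / std::fabs(dx);
  } else { tmx = inf; tdx = inf; }
  if (std::fabs(dy) > 1e-300) {
    double by = g->y0 + (iy + (sy > 0 ? 1 : 0)) * g->cell;
    tmy = (by - oy) / dy;
    tdy = g->cell / std::fabs(dy);
  } else { tmy = inf; tdy = inf; }
  if (std::fabs(dz) > 1e-300) {
    double bz = g->z0 + (iz + (sz > 0 ? 1 : 0)) * g->cell;
    tmz = (bz - oz) / dz;
    tdz = g->cell / std::fabs(dz);
  } else { tmz = inf; tdz = inf; }

  while (true) {
    const std::vector<int>& ids = g->cells[g->cell_index(ix, iy, iz)];
    for (size_t k = 0; k < ids.size(); ++k) {
      const int id = ids[k];
      if (g->stamp[id] != gen) {
        g->stamp[id] = gen;
        cand.push_back(id);
      }
    }
    double tnext;
    if (tmx <= tmy && tmx <= tmz) {
      tnext = tmx; ix += sx; tmx += tdx;
      if (ix < 0 || ix >= g->nx) break;
    } else if (tmy <= tmz) {
      tnext = tmy; iy += sy; tmy += tdy;
      if (iy < 0 || iy >= g->ny) break;
    } else {
      tnext = tmz; iz += sz; tmz += tdz;
      if (iz < 0 || iz >= g->nz) break;
    }
    if (tnext > t_hi) break;
  }

  // Exact sphere intersections for the candidates.
  std::vector<double> he, hx, id_out;
  std::vector<int> order;
  std::vector<double> t_entry, t_exit;
  std::vector<int> hit_id;
  for (size_t k = 0; k < cand.size(); ++k) {
    const int i = cand[k];
    const double mx = ox - g->cx[i], my = oy - g->cy[i], mz = oz - g->cz[i];
    const double b = mx * dx + my * dy + mz * dz;
    const double c = mx * mx + my * my + mz * mz - g->rad[i] * g->rad[i];
    const double disc = b * b - c;
    if (disc <= 0) continue;          // grazing counts as a miss
    const double s = std::sqrt(disc);
    const double t2 = -b + s;
    if (t2 <= 0) continue;            // sphere behind the origin
    double t1 = -b - s;
    if (t1 < 0) t1 = 0.0;             // origin inside the sphere
    if (t1 >= tmax) continue;
    hit_id.push_back(i);
    t_entry.push_back(t1);
    t_exit.push_back(std::min(t2, tmax));
  }

  const int m = (int)hit_id.size();
  order.resize(m);
  for (int i = 0; i < m; ++i) order[i] = i;
  std::sort(order.begin(), order.end(), [&](int a, int b2) {
    if (t_entry[a] != t_entry[b2]) return t_entry[a] < t_entry[b2];
    return hit_id[a] < hit_id[b2];
  });

  NumericMatrix out(m, 3);
  for (int i = 0; i < m; ++i) {
    out(i, 0) = hit_id[order[i]] + 1;  // 1-based for R
    out(i, 1) = t_entry[order[i]];
    out(i, 2) = t_exit[order[i]];
  }
  return out;
}
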