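// Subcellular-element mechanics kernels and the morphogen PDE stepper.
//
// Geometry conventions: positions in micrometres, the basement membrane is
// the plane z = 0, the domain may be periodic in x and y (minimum-image
// distances). All pair interactions are assembled from a candidate pair
// list built by cell-list binning; intracellular springs act between all
// element pairs of a cell and are assembled independently of that list.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double wrap(double d, double L) {
  // minimum-image convention for one periodic coordinate
  if (d > 0.5 * L) d -= L;
  else if (d < -0.5 * L) d += L;
  return d;
}

static inline double wrap_into(double x, double L) {
  // reduce a coordinate into [0, L) (floor-based; avoids fmod)
  return x - L * std::floor(x / L);
}

// Candidate pair list: every element pair with separation <= cutoff is
// guaranteed to appear (bins of edge >= cutoff, half stencil).
// [[Rcpp::export(name = ".build_pairs_cpp")]]
IntegerMatrix build_pairs_cpp(NumericMatrix pos, double cutoff,
                              double Lx, double Ly, bool periodic_xy) {
  const int n = pos.nrow();
  if (n < 2) return IntegerMatrix(0, 2);
  const double c2 = cutoff * cutoff;

  double zmin = pos(0, 2), zmax = pos(0, 2);
  for (int i = 1; i < n; ++i) {
    zmin = std::min(zmin, pos(i, 2));
    zmax = std::max(zmax, pos(i, 2));
  }
  int nbx = std::max(1, (int)std::floor(Lx / cutoff));
  int nby = std::max(1, (int)std::floor(Ly / cutoff));
  int nbz = std::max(1, (int)std::floor((zmax - zmin) / cutoff) + 1);

  // with fewer than 3 bins along a periodic axis the wrapped half stencil
  // would revisit bins; fall back to the quadratic sweep
  if (n < 64 || (periodic_xy && (nbx < 3 || nby < 3))) {
    std::vector<int> pi, pj;
    for (int i = 0; i + 1 < n; ++i) for (int j = i + 1; j < n; ++j) {
      double dx = pos(i, 0) - pos(j, 0), dy = pos(i, 1) - pos(j, 1);
      double dz = pos(i, 2) - pos(j, 2);
      if (periodic_xy) { dx = wrap(dx, Lx); dy = wrap(dy, Ly); }
      if (dx * dx + dy * dy + dz * dz <= c2) { pi.push_back(i); pj.push_back(j); }
    }
    IntegerMatrix out(pi.size(), 2);
    for (size_t k = 0; k < pi.size(); ++k) { out(k, 0) = pi[k]; out(k, 1) = pj[k]; }
    return out;
  }

  std::vector<std::vector<int> > bins((size_t)nbx * nby * nbz);
  std::vector<int> bx(n), by(n), bz(n);
  for (int i = 0; i < n; ++i) {
    double x = pos(i, 0), y = pos(i, 1);
    if (periodic_xy) {
      x = wrap_into(x, Lx);
      y = wrap_into(y, Ly);
    }
    int ix = std::min(nbx - 1, std::max(0, (int)std::floor(x / Lx * nbx)));
    int iy = std::min(nby - 1, std::max(0, (int)std::floor(y / Ly * nby)));
    int iz = std::min(nbz - 1, std::max(0, (int)std::floor((pos(i, 2) - zmin) / cutoff)));
    bx[i] = ix; by[i] = iy; bz[i] = iz;
    bins[(size_t)ix + (size_t)nbx * (iy + (size_t)nby * iz)].push_back(i);
  }

  std::vector<int> pi, pj;
  pi.reserve((size_t)n * 8); pj.reserve((size_t)n * 8);
  for (int ix = 0; ix < nbx; ++ix) for (int iy = 0; iy < nby; ++iy)
  for (int iz = 0; iz < nbz; ++iz) {
    const std::vector<int>& a = bins[(size_t)ix + (size_t)nbx * (iy + (size_t)nby * iz)];
    if (a.empty()) continue;
    for (int dx = -1; dx <= 1; ++dx) for (int dy = -1; dy <= 1; ++dy)
    for (int dz = 0; dz <= 1; ++dz) {
      if (dz == 0 && (dx < 0 || (dx == 0 && dy < 0))) continue; // half stencil
      int jx = ix + dx, jy = iy + dy, jz = iz + dz;
      if (jz >= nbz) continue;
      if (periodic_xy) { jx = (jx + nbx) % nbx; jy = (jy + nby) % nby; }
      else if (jx < 0 || jx >= nbx || jy < 0 || jy >= nby) continue;
      bool self = (jx == ix && jy == iy && jz == iz);
      const std::vector<int>& b = bins[(size_t)jx + (size_t)nbx * (jy + (size_t)nby * jz)];
      for (size_t u = 0; u < a.size(); ++u) {
        size_t v0 = self ? u + 1 : 0;
        for (size_t v = v0; v < b.size(); ++v) {
          int i = a[u], j = b[v];
          double ddx = pos(i, 0) - pos(j, 0), ddy = pos(i, 1) - pos(j, 1);
          double ddz = pos(i, 2) - pos(j, 2);
          if (periodic_xy) { ddx = wrap(ddx, Lx); ddy = wrap(ddy, Ly); }
          if (ddx * ddx + ddy * ddy + ddz * ddz <= c2) { pi.push_back(i); pj.push_back(j); }
        }
      }
    }
  }
  IntegerMatrix out(pi.size(), 2);
  for (size_t k = 0; k < pi.size(); ++k) { out(k, 0) = pi[k]; out(k, 1) = pj[k]; }
  return out;
}

// Force assembly over a candidate pair list.
//
// cell:     integer cell id per element
// aclass:   adhesion class per element (0 basal, 1 spinous, 2 granular);
//           Fa applies within a class, Fb across classes
// adherent: 1 for membrane-adherent elements (these feel the membrane pull)
// Returns forces (n x 3), total potential energy, and counts of clamped
// short-range LJ evaluations and skipped coincident pairs.
// [[Rcpp::export(name = ".assemble_forces_cpp")]]
List assemble_forces_cpp(NumericMatrix pos, IntegerVector cell,
                         IntegerVector aclass, IntegerVector adherent,
                         IntegerMatrix pairs,
                         double mu_spring, double r0,
                         double eps, double sigma, double Fa, double Fb,
                         double inter_cutoff, double f_clamp,
                         double eps_external, double membrane_cutoff,
                         double Lx, double Ly, bool periodic_xy) {
  const int n = pos.nrow();
  NumericMatrix F(n, 3);
  double energy = 0.0;
  int n_clamped = 0, n_coincident = 0;
  const double rfloor = 0.05 * sigma;
  const double cut2 = inter_cutoff * inter_cutoff;

  // intercellular Lennard-Jones over the candidate list
  for (int k = 0; k < pairs.nrow(); ++k) {
    int i = pairs(k, 0), j = pairs(k, 1);
    if (cell[i] == cell[j]) continue;
    double dx = pos(i, 0) - pos(j, 0), dy = pos(i, 1) - pos(j, 1);
    double dz = pos(i, 2) - pos(j, 2);
    if (periodic_xy) { dx = wrap(dx, Lx); dy = wrap(dy, Ly); }
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 > cut2) continue;
    double r = std::sqrt(r2);
    if (r < 1e-12) { ++n_coincident; continue; }
    double reval = r;
    if (r < rfloor) { reval = rfloor; ++n_clamped; }
    double Fab = (aclass[i] == aclass[j]) ? Fa : Fb;
    double sr6 = std::pow(sigma / reval, 6.0), sr12 = sr6 * sr6;
    energy += Fab * eps * (sr12 - sr6);
    // dV/dr = Fab*eps*(-12 sr12 + 6 sr6)/r ; force on i = -dV/dr * unit(i-j)
    double fmag = Fab * eps * (12.0 * sr12 - 6.0 * sr6) / reval; // >0 repulsive
    if (fmag > f_clamp) { fmag = f_clamp; ++n_clamped; }
    else if (fmag < -f_clamp) fmag = -f_clamp;
    double fr = fmag / r;
    F(i, 0) += fr * dx; F(i, 1) += fr * dy; F(i, 2) += fr * dz;
    F(j, 0) -= fr * dx; F(j, 1) -= fr * dy; F(j, 2) -= fr * dz;
  }

  // intracellular all-pair springs, grouped by cell
  std::unordered_map<int, std::vector<int> > groups;
  for (int i = 0; i < n; ++i) groups[cell[i]].push_back(i);
  for (std::unordered_map<int, std::vector<int> >::const_iterator it = groups.begin();
       it != groups.end(); ++it) {
    const std::vector<int>& g = it->second;
    for (size_t u = 0; u + 1 < g.size(); ++u) for (size_t v = u + 1; v < g.size(); ++v) {
      int i = g[u], j = g[v];
      double dx = pos(i, 0) - pos(j, 0), dy = pos(i, 1) - pos(j, 1);
      double dz = pos(i, 2) - pos(j, 2);
      if (periodic_xy) { dx = wrap(dx, Lx); dy = wrap(dy, Ly); }
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r < 1e-12) { ++n_coincident; continue; }
      energy += 0.5 * mu_spring * (r - r0) * (r - r0);
      double fr = -mu_spring * (r - r0) / r; // attractive when stretched
      F(i, 0) += fr * dx; F(i, 1) += fr * dy; F(i, 2) += fr * dz;
      F(j, 0) -= fr * dx; F(j, 1) -= fr * dy; F(j, 2) -= fr * dz;
    }
  }

  // basement-membrane adhesion: V = eps_external * |z| within the cutoff,
  // applied only to flagged (membrane-adherent) elements
  if (eps_external > 0) {
    for (int i = 0; i < n; ++i) {
      if (!adherent[i]) continue;
      double z = pos(i, 2);
      double az = std::fabs(z);
      if (az > membrane_cutoff) continue;
      energy += eps_external * az;
      if (az > 1e-12) F(i, 2) -= eps_external * (z > 0 ? 1.0 : -1.0);
    }
  }

  return List::create(_["forces"] = F, _["energy"] = energy,
                      _["n_clamped"] = n_clamped,
                      _["n_coincident"] = n_coincident);
}

// Forward-Euler update of the morphogen field in conservative flux form:
//   s_t = div(D grad s) + src - ds * s
// with face diffusivities averaged between adjacent voxels, zero-flux
// boundaries (periodic in x/y when requested), and clipping at zero.
// s, D, src are nx*ny*nz arrays in column-major voxel order.
// [[Rcpp::export(name = ".step_field_cpp")]]
List step_field_cpp(NumericVector s, NumericVector D, NumericVector src,
                    double ds_decay, double dt, int n_substeps,
                    double h, int nx, int ny, int nz, bool periodic_xy) {
  NumericVector cur = clone(s);
  NumericVector nxt((size_t)nx * ny * nz);
  const double ih2 = 1.0 / (h * h);
  long clipped = 0;
#define IDX(i, j, k) ((size_t)(i) + (size_t)nx * ((j) + (size_t)ny * (k)))
  for (int step = 0; step < n_substeps; ++step) {
    for (int k = 0; k < nz; ++k) for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      size_t c = IDX(i, j, k);
      double sc = cur[c], Dc = D[c], lap = 0.0;
      // x faces
      if (i + 1 < nx) { size_t u = IDX(i + 1, j, k); lap += 0.5 * (Dc + D[u]) * (cur[u] - sc); }
      else if (periodic_xy) { size_t u = IDX(0, j, k); lap += 0.5 * (Dc + D[u]) * (cur[u] - sc); }
      if (i > 0) { size_t u = IDX(i - 1, j, k); lap += 0.5 * (Dc + D[u]) * (cur[u] - sc); }
      else if (periodic_xy) { size_t u = IDX(nx - 1, j, k); lap += 0.5 * (Dc + D[u]) * (cur[u] - sc); }
      // y faces
      if (j + 1 < ny) { size_t u = IDX(i, j + 1, k); lap += 0.5 * (Dc + D[u]) * (cur[u] - sc); }
      else if (periodic_xy) { size_t u = IDX(i, 0, k); lap += 0.5 * (Dc + D[u]) * (cur[u] - sc); }
      if (j > 0) { size_t u = IDX(i, j - 1, k); lap += 0.5 * (Dc + D[u]) * (cur[u] - sc); }
      else if (periodic_xy) { size_t u = IDX(i, ny - 1, k); lap += 0.5 * (Dc + D[u]) * (cur[u] - sc); }
      // z faces (always zero-flux at domain top/bottom)
      if (k + 1 < nz) { size_t u = IDX(i, j, k + 1); lap += 0.5 * (Dc + D[u]) * (cur[u] - sc); }
      if (k > 0) { size_t u = IDX(i, j, k - 1); lap += 0.5 * (Dc + D[u]) * (cur[u] - sc); }
      double val = sc + dt * (lap * ih2 + src[c] - ds_decay * sc);
      if (val < 0) { val = 0; ++clipped; }
      nxt[c] = val;
    }
    std::swap(cur, nxt);
  }
#undef IDX
  return List::create(_["s"] = cur, _["n_clipped"] = (double)clipped);
}

// Fused neighbor search + force assembly (no pair list materialised).
// Semantics identical to build_pairs_cpp + assemble_forces_cpp. Elements
// are spatially sorted into contiguous bin ranges for cache locality and
// the common Lennard-Jones path avoids sqrt (the clamp test compares
// squared magnitudes; the rare clamped branch takes the slow path).
// [[Rcpp::export(name = ".compute_forces_cpp")]]
List compute_forces_cpp(NumericMatrix pos, IntegerVector cell,
                        IntegerVector aclass, IntegerVector adherent,
                        double mu_spring, double r0,
                        double eps, double sigma, double Fa, double Fb,
                        double inter_cutoff, double f_clamp,
                        double eps_external, double membrane_cutoff,
                        double Lx, double Ly, bool periodic_xy) {
  const int n = pos.nrow();
  NumericMatrix F(n, 3);
  double energy = 0.0;
  int n_clamped = 0, n_coincident = 0;
  const double rfloor = 0.05 * sigma;
  const double rfloor2 = rfloor * rfloor;
  const double cut2 = inter_cutoff * inter_cutoff;
  const double s2 = sigma * sigma;
  const double fc2 = f_clamp * f_clamp;

  std::vector<double> X(n), Y(n), Z(n), FX(n, 0.0), FY(n, 0.0), FZ(n, 0.0);
  std::vector<int> C(n), A(n);
  std::vector<int> perm(n);

  double zmin = 0, zmax = 0;
  if (n > 0) {
    zmin = zmax = pos(0, 2);
    for (int i = 1; i < n; ++i) {
      zmin = std::min(zmin, pos(i, 2));
      zmax = std::max(zmax, pos(i, 2));
    }
  }
  const double bs = inter_cutoff / 2.0; // half-cutoff bins, radius-2 stencil
  const int R = 2;
  int nbx = std::max(1, (int)std::floor(Lx / bs));
  int nby = std::max(1, (int)std::floor(Ly / bs));
  int nbz = std::max(1, (int)std::floor((zmax - zmin) / bs) + 1);
  bool brute = (n < 64 || (periodic_xy && (nbx < 2 * R + 1 || nby < 2 * R + 1)));

  std::vector<int> bin_start, bin_count, bin_of;
  if (!brute) {
    size_t nb = (size_t)nbx * nby * nbz;
    bin_count.assign(nb, 0);
    bin_of.resize(n);
    for (int i = 0; i < n; ++i) {
      double x = pos(i, 0), y = pos(i, 1);
      if (periodic_xy) { x = wrap_into(x, Lx); y = wrap_into(y, Ly); }
      int ix = std::min(nbx - 1, std::max(0, (int)std::floor(x / Lx * nbx)));
      int iy = std::min(nby - 1, std::max(0, (int)std::floor(y / Ly * nby)));
      int iz = std::min(nbz - 1, std::max(0, (int)std::floor((pos(i, 2) - zmin) / bs)));
      int b = ix + nbx * (iy + nby * iz);
      bin_of[i] = b;
      ++bin_count[b];
    }
    bin_start.assign(nb + 1, 0);
    for (size_t b = 0; b < nb; ++b) bin_start[b + 1] = bin_start[b] + bin_count[b];
    std::vector<int> cursor(bin_start.begin(), bin_start.end() - 1);
    for (int i = 0; i < n; ++i) perm[cursor[bin_of[i]]++] = i;
  } else {
    for (int i = 0; i < n; ++i) perm[i] = i;
  }
  for (int k = 0; k < n; ++k) {
    int i = perm[k];
    X[k] = pos(i, 0); Y[k] = pos(i, 1); Z[k] = pos(i, 2);
    C[k] = cell[i]; A[k] = aclass[i];
  }

  // LJ between candidate sorted indices u < v (different cells)
  #define LJ_PAIR(u, v) do { \
    if (C[(u)] != C[(v)]) { \
      double dx = X[(u)] - X[(v)], dy = Y[(u)] - Y[(v)], dz = Z[(u)] - Z[(v)]; \
      if (periodic_xy) { dx = wrap(dx, Lx); dy = wrap(dy, Ly); } \
      double r2 = dx * dx + dy * dy + dz * dz; \
      if (r2 <= cut2) { \
        double Fab = (A[(u)] == A[(v)]) ? Fa : Fb; \
        if (r2 >= rfloor2) { \
          double inv = 1.0 / r2; \
          double q = s2 * inv, sr6 = q * q * q, sr12 = sr6 * sr6; \
          energy += Fab * eps * (sr12 - sr6); \
          double num = Fab * eps * (12.0 * sr12 - 6.0 * sr6); \
          double fr; \
          if (num * num > fc2 * r2) { /* rare clamped branch */ \
            ++n_clamped; \
            fr = (num > 0 ? f_clamp : -f_clamp) / std::sqrt(r2); \
          } else fr = num * inv; \
          FX[(u)] += fr * dx; FY[(u)] += fr * dy; FZ[(u)] += fr * dz; \
          FX[(v)] -= fr * dx; FY[(v)] -= fr * dy; FZ[(v)] -= fr * dz; \
        } else if (r2 < 1e-24) { ++n_coincident; } \
        else { /* deep core: evaluate at the distance floor, clamped */ \
          ++n_clamped; \
          double q = s2 / rfloor2, sr6 = q * q * q, sr12 = sr6 * sr6; \
          energy += Fab * eps * (sr12 - sr6); \
          double fmag = Fab * eps * (12.0 * sr12 - 6.0 * sr6) / rfloor; \
          if (fmag > f_clamp) fmag = f_clamp; \
          double fr = fmag / std::sqrt(r2); \
          FX[(u)] += fr * dx; FY[(u)] += fr * dy; FZ[(u)] += fr * dz; \
          FX[(v)] -= fr * dx; FY[(v)] -= fr * dy; FZ[(v)] -= fr * dz; \
        } \
      } \
    } \
  } while (0)

  if (brute) {
    for (int u = 0; u + 1 < n; ++u) for (int v = u + 1; v < n; ++v) LJ_PAIR(u, v);
  } else {
    for (int ix = 0; ix < nbx; ++ix) for (int iy = 0; iy < nby; ++iy)
    for (int iz = 0; iz < nbz; ++iz) {
      int b = ix + nbx * (iy + nby * iz);
      int as0 = bin_start[b], ae = bin_start[b + 1];
      if (as0 == ae) continue;
      for (int dz = 0; dz <= R; ++dz)
      for (int dy = -R; dy <= R; ++dy) for (int dx = -R; dx <= R; ++dx) {
        // visit each unordered bin pair once (lexicographically positive
        // offsets plus the self bin)
        if (dz == 0 && (dy < 0 || (dy == 0 && dx < 0))) continue;
        int jx = ix + dx, jy = iy + dy, jz = iz + dz;
        if (jz >= nbz) continue;
        if (periodic_xy) { jx = (jx + nbx) % nbx; jy = (jy + nby) % nby; }
        else if (jx < 0 || jx >= nbx || jy < 0 || jy >= nby) continue;
        bool self = (dx == 0 && dy == 0 && dz == 0);
        int b2 = jx + nbx * (jy + nby * jz);
        int bs0 = bin_start[b2], be = bin_start[b2 + 1];
        for (int u = as0; u < ae; ++u) {
          int v0 = self ? u + 1 : bs0;
          for (int v = v0; v < be; ++v) LJ_PAIR(u, v);
        }
      }
    }
  }
  #undef LJ_PAIR

  // scatter sorted forces back to original order
  for (int k = 0; k < n; ++k) {
    int i = perm[k];
    F(i, 0) = FX[k]; F(i, 1) = FY[k]; F(i, 2) = FZ[k];
  }

  // intracellular all-pair springs (original order)
  std::unordered_map<int, std::vector<int> > groups;
  for (int i = 0; i < n; ++i) groups[cell[i]].push_back(i);
  for (std::unordered_map<int, std::vector<int> >::const_iterator it = groups.begin();
       it != groups.end(); ++it) {
    const std::vector<int>& g = it->second;
    for (size_t u = 0; u + 1 < g.size(); ++u) for (size_t v = u + 1; v < g.size(); ++v) {
      int i = g[u], j = g[v];
      double dx = pos(i, 0) - pos(j, 0), dy = pos(i, 1) - pos(j, 1);
      double dz = pos(i, 2) - pos(j, 2);
      if (periodic_xy) { dx = wrap(dx, Lx); dy = wrap(dy, Ly); }
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r < 1e-12) { ++n_coincident; continue; }
      energy += 0.5 * mu_spring * (r - r0) * (r - r0);
      double fr = -mu_spring * (r - r0) / r;
      F(i, 0) += fr * dx; F(i, 1) += fr * dy; F(i, 2) += fr * dz;
      F(j, 0) -= fr * dx; F(j, 1) -= fr * dy; F(j, 2) -= fr * dz;
    }
  }

  if (eps_external > 0) {
    for (int i = 0; i < n; ++i) {
      if (!adherent[i]) continue;
      double z = pos(i, 2), az = std::fabs(z);
      if (az > membrane_cutoff) continue;
      energy += eps_external * az;
      if (az > 1e-12) F(i, 2) -= eps_external * (z > 0 ? 1.0 : -1.0);
    }
  }

  return List::create(_["forces"] = F, _["energy"] = energy,
                      _["n_clamped"] = n_clamped,
                      _["n_coincident"] = n_coincident);
}

// Overdamped position update with the displacement bound: attempts the
// full step; if any element would move farther than bound, the time step
// is halved (same noise, rescaled) until it fits, and the remainder of
// the step is consumed in further bounded chunks with fresh noise.
// Noise is drawn from R's RNG so runs stay seed-reproducible.
// [[Rcpp::export(name = ".step_update_cpp")]]
List step_update_cpp(NumericMatrix pos, NumericMatrix forces,
                     double mobility, double noise_amp, double dt,
                     double bound) {
  const int n = pos.nrow();
  NumericMatrix out = clone(pos);
  const double b2 = bound * bound;
  int halvings = 0;
  double taken = 0.0;
  std::vector<double> nx(n), ny(n), nz(n);
  GetRNGstate();
  while (taken < dt - 1e-12) {
    double want = dt - taken;
    if (noise_amp > 0) {
      for (int i = 0; i < n; ++i) { nx[i] = norm_rand(); ny[i] = norm_rand(); nz[i] = norm_rand(); }
    } else {
      std::fill(nx.begin(), nx.end(), 0.0);
      std::fill(ny.begin(), ny.end(), 0.0);
      std::fill(nz.begin(), nz.end(), 0.0);
    }
    double h = want;
    int k = 0;
    for (; k < 20; ++k) {
      double sh = std::sqrt(h) * noise_amp;
      double worst = 0.0;
      for (int i = 0; i < n; ++i) {
        double dx = mobility * forces(i, 0) * h + sh * nx[i];
        double dy = mobility * forces(i, 1) * h + sh * ny[i];
        double dz = mobility * forces(i, 2) * h + sh * nz[i];
        double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 > worst) worst = d2;
      }
      if (worst <= b2 || n == 0) break;
      h *= 0.5;
      ++halvings;
    }
    double sh = std::sqrt(h) * noise_amp;
    for (int i = 0; i < n; ++i) {
      out(i, 0) += mobility * forces(i, 0) * h + sh * nx[i];
      out(i, 1) += mobility * forces(i, 1) * h + sh * ny[i];
      out(i, 2) += mobility * forces(i, 2) * h + sh * nz[i];
    }
    taken += h;
    if (k >= 20) break; // bail out; caller warns
  }
  PutRNGstate();
  return List::create(_["pos"] = out, _["dt_taken"] = taken,
                      _["n_halvings"] = halvings);
}
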