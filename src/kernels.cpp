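#include <Rcpp.h>
#include <array>
#include <cmath>
#include <queue>
#include <vector>
using namespace Rcpp;

// 0-based trilinear sample at fractional voxel index (x,y,z); fill outside grid
static inline double interp3(const double* v, const int nx, const int ny,
                             const int nz, double x, double y, double z,
                             const double fill, const bool nearest) {
  if (nearest) {
    const long i = (long)std::llround(x), j = (long)std::llround(y),
               k = (long)std::llround(z);
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return fill;
    return v[i + (long)nx * (j + (long)ny * k)];
  }
  if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1)
    return fill;
  long i0 = (long)std::floor(x), j0 = (long)std::floor(y),
       k0 = (long)std::floor(z);
  if (i0 == nx - 1) i0--;
  if (j0 == ny - 1) j0--;
  if (k0 == nz - 1) k0--;
  if (nx == 1) i0 = 0;
  if (ny == 1) j0 = 0;
  if (nz == 1) k0 = 0;
  const double fx = x - i0, fy = y - j0, fz = z - k0;
  const long i1 = (nx == 1) ? i0 : i0 + 1, j1 = (ny == 1) ? j0 : j0 + 1,
             k1 = (nz == 1) ? k0 : k0 + 1;
#define V(i, j, k) v[(i) + (long)nx * ((j) + (long)ny * (k))]
  const double c00 = V(i0, j0, k0) * (1 - fx) + V(i1, j0, k0) * fx;
  const double c10 = V(i0, j1, k0) * (1 - fx) + V(i1, j1, k0) * fx;
  const double c01 = V(i0, j0, k1) * (1 - fx) + V(i1, j0, k1) * fx;
  const double c11 = V(i0, j1, k1) * (1 - fx) + V(i1, j1, k1) * fx;
#undef V
  const double c0 = c00 * (1 - fy) + c10 * fy;
  const double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// Resample src onto a target grid. The source fractional index for target
// voxel (i,j,k) is ((M %*% q + b) - src_origin) / src_spacing with
// q = tgt_origin + (i,j,k) * tgt_spacing (world mm). M, b encode the inverse
// of the rigid transform mapping source space into target space.
// [[Rcpp::export]]
NumericVector cpp_resample(NumericVector src, IntegerVector sdim,
                           NumericVector sspc, NumericVector sorg,
                           IntegerVector tdim, NumericVector tspc,
                           NumericVector torg, NumericMatrix M,
                           NumericVector b, double fill, bool nearest) {
  const int nx = sdim[0], ny = sdim[1], nz = sdim[2];
  const int tx = tdim[0], ty = tdim[1], tz = tdim[2];
  NumericVector out((long)tx * ty * tz);
  const double* v = REAL(src);
  long idx = 0;
  for (int k = 0; k < tz; ++k) {
    const double qz = torg[2] + k * tspc[2];
    for (int j = 0; j < ty; ++j) {
      const double qy = torg[1] + j * tspc[1];
      for (int i = 0; i < tx; ++i, ++idx) {
        const double qx = torg[0] + i * tspc[0];
        const double px = M(0, 0) * qx + M(0, 1) * qy + M(0, 2) * qz + b[0];
        const double py = M(1, 0) * qx + M(1, 1) * qy + M(1, 2) * qz + b[1];
        const double pz = M(2, 0) * qx + M(2, 1) * qy + M(2, 2) * qz + b[2];
        out[idx] = interp3(v, nx, ny, nz, (px - sorg[0]) / sspc[0],
                           (py - sorg[1]) / sspc[1], (pz - sorg[2]) / sspc[2],
                           fill, nearest);
      }
    }
  }
  return out;
}

// Trilinear (or nearest) sampling at arbitrary world points, rows of pts (mm).
// [[Rcpp::export]]
NumericVector cpp_interp_points(NumericVector src, IntegerVector sdim,
                                NumericVector sspc, NumericVector sorg,
                                NumericMatrix pts, double fill, bool nearest) {
  const int nx = sdim[0], ny = sdim[1], nz = sdim[2];
  const int n = pts.nrow();
  NumericVector out(n);
  const double* v = REAL(src);
  for (int r = 0; r < n; ++r)
    out[r] = interp3(v, nx, ny, nz, (pts(r, 0) - sorg[0]) / sspc[0],
                     (pts(r, 1) - sorg[1]) / sspc[1],
                     (pts(r, 2) - sorg[2]) / sspc[2], fill, nearest);
  return out;
}

// Global gamma index. offsets: Nx3 search displacements (mm) sorted by
// ascending |offset|; dist2 = (|offset|/dta)^2, precomputed. dd_abs is the
// absolute dose tolerance (Gy). evalmask: 1 = compute gamma at this reference
// voxel. Early termination: once the pure distance term exceeds the current
// best squared gamma no further offset can improve it.
// [[Rcpp::export]]
NumericVector cpp_gamma(NumericVector ref, NumericVector evl,
                        IntegerVector dim, NumericVector spc,
                        NumericVector org, NumericMatrix offsets,
                        NumericVector dist2, double dd_abs,
                        IntegerVector evalmask) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const long n = (long)nx * ny * nz;
  const int noff = offsets.nrow();
  NumericVector out(n, NA_REAL);
  const double* ev = REAL(evl);
  long idx = 0;
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i, ++idx) {
        if (!evalmask[idx]) continue;
        const double dr = ref[idx];
        double best = R_PosInf;
        for (int o = 0; o < noff; ++o) {
          if (dist2[o] >= best) break;
          const double x = i + offsets(o, 0) / spc[0];
          const double y = j + offsets(o, 1) / spc[1];
          const double z = k + offsets(o, 2) / spc[2];
          const double de = interp3(ev, nx, ny, nz, x, y, z, NA_REAL, false);
          if (ISNA(de)) continue;
          const double dd = (de - dr) / dd_abs;
          const double g2 = dist2[o] + dd * dd;
          if (g2 < best) best = g2;
        }
        out[idx] = std::sqrt(best);
      }
    }
  }
  return out;
}

// 3D connected components, 6- or 26-connectivity, BFS labelling.
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dim,
                          int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const long n = (long)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<std::array<int, 3>> nb;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        const int man = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && man > 1) continue;
        nb.push_back({dx, dy, dz});
      }
  int cur = 0;
  std::queue<long> q;
  for (long s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    lab[s] = ++cur;
    q.push(s);
    while (!q.empty()) {
      const long p = q.front();
      q.pop();
      const int i = p % nx, j = (p / nx) % ny, k = p / ((long)nx * ny);
      for (const auto& d : nb) {
        const int ii = i + d[0], jj = j + d[1], kk = k + d[2];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
          continue;
        const long pp = ii + (long)nx * (jj + (long)ny * kk);
        if (mask[pp] && !lab[pp]) {
          lab[pp] = cur;
          q.push(pp);
        }
      }
    }
  }
  return lab;
}

// Binary dilation by an explicit voxel-offset structuring element (Nx3 int).
// [[Rcpp::export]]
LogicalVector cpp_dilate(LogicalVector mask, IntegerVector dim,
                         IntegerMatrix offs) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const long n = (long)nx * ny * nz;
  LogicalVector out(n, false);
  const int noff = offs.nrow();
  for (long p = 0; p < n; ++p) {
    if (!mask[p]) continue;
    const int i = p % nx, j = (p / nx) % ny, k = p / ((long)nx * ny);
    for (int o = 0; o < noff; ++o) {
      const int ii = i + offs(o, 0), jj = j + offs(o, 1), kk = k + offs(o, 2);
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
        continue;
      out[ii + (long)nx * (jj + (long)ny * kk)] = true;
    }
  }
  return out;
}

// Parallel-beam analytic dose: per voxel, exponential attenuation along the
// radiological depth (ray-marched density integral entering along -dir) times
// a flat circular field of radius field_r with a Gaussian-smoothed edge
// (sigma mm) around the axis through axis_pt along dir.
// [[Rcpp::export]]
NumericVector cpp_beam_dose(NumericVector dens, IntegerVector dim,
                            NumericVector spc, NumericVector org,
                            NumericVector dir, NumericVector axis_pt,
                            double mu, double field_r, double sigma,
                            double step) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double* dv = REAL(dens);
  NumericVector out((long)nx * ny * nz);
  // max ray length: grid diagonal
  const double ex = (nx - 1) * spc[0], ey = (ny - 1) * spc[1],
               ez = (nz - 1) * spc[2];
  const double diag = std::sqrt(ex * ex + ey * ey + ez * ez);
  const int nstep = (int)std::ceil(diag / step);
  long idx = 0;
  for (int k = 0; k < nz; ++k) {
    const double pz = org[2] + k * spc[2];
    for (int j = 0; j < ny; ++j) {
      const double py = org[1] + j * spc[1];
      for (int i = 0; i < nx; ++i, ++idx) {
        const double px = org[0] + i * spc[0];
        // radiological depth: integrate density upstream (towards source)
        double depth = 0.0;
        for (int s = 1; s <= nstep; ++s) {
          const double qx = px - dir[0] * step * s;
          const double qy = py - dir[1] * step * s;
          const double qz = pz - dir[2] * step * s;
          const double x = (qx - org[0]) / spc[0];
          const double y = (qy - org[1]) / spc[1];
          const double z = (qz - org[2]) / spc[2];
          if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 ||
              z > nz - 1)
            break;
          depth += interp3(dv, nx, ny, nz, x, y, z, 0.0, false) * step;
        }
        // perpendicular distance to the beam axis
        const double wx = px - axis_pt[0], wy = py - axis_pt[1],
                     wz = pz - axis_pt[2];
        const double t = wx * dir[0] + wy * dir[1] + wz * dir[2];
        const double rx = wx - t * dir[0], ry = wy - t * dir[1],
                     rz = wz - t * dir[2];
        const double r = std::sqrt(rx * rx + ry * ry + rz * rz);
        const double prof = 0.5 * std::erfc((r - field_r) / (M_SQRT2 * sigma));
        out[idx] = std::exp(-mu * depth) * prof;
      }
    }
  }
  return out;
}
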