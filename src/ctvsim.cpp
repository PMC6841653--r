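#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double BIG = 1e20;

// 1-D squared-distance transform (lower envelope of parabolas) on a grid with
// physical sample spacing w.  f: input squared distances, d: output.
static void dt1d(const double* f, double* d, int n, double w,
                 std::vector<double>& z, std::vector<int>& v) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; q++) {
    double xq = q * w;
    double s;
    while (true) {
      double xv = v[k] * w;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * (xq - xv));
      if (s <= z[k]) {
        k--;
      } else {
        break;
      }
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    double x = q * w;
    while (z[k + 1] < x) k++;
    double xv = v[k] * w;
    d[q] = (x - xv) * (x - xv) + f[v[k]];
  }
}

// Exact anisotropic Euclidean distance transform (mm) of a binary mask:
// distance from each foreground voxel to the nearest background voxel centre,
// 0 on background.  Separable Felzenszwalb-Huttenlocher over the three axes.
// [[Rcpp::export(name = ".edt_cpp")]]
NumericVector edt_cpp(IntegerVector mask, IntegerVector dim, NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> g(n);
  for (R_xlen_t i = 0; i < n; i++) g[i] = mask[i] ? BIG : 0.0;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // along x (fastest-varying)
  for (int kz = 0; kz < nz; kz++)
    for (int ky = 0; ky < ny; ky++) {
      R_xlen_t off = (R_xlen_t)kz * nx * ny + (R_xlen_t)ky * nx;
      for (int i = 0; i < nx; i++) f[i] = g[off + i];
      dt1d(f.data(), d.data(), nx, spacing[0], z, v);
      for (int i = 0; i < nx; i++) g[off + i] = d[i];
    }
  // along y
  for (int kz = 0; kz < nz; kz++)
    for (int kx = 0; kx < nx; kx++) {
      R_xlen_t off = (R_xlen_t)kz * nx * ny + kx;
      for (int j = 0; j < ny; j++) f[j] = g[off + (R_xlen_t)j * nx];
      dt1d(f.data(), d.data(), ny, spacing[1], z, v);
      for (int j = 0; j < ny; j++) g[off + (R_xlen_t)j * nx] = d[j];
    }
  // along z
  R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (int ky = 0; ky < ny; ky++)
    for (int kx = 0; kx < nx; kx++) {
      R_xlen_t off = (R_xlen_t)ky * nx + kx;
      for (int k = 0; k < nz; k++) f[k] = g[off + (R_xlen_t)k * nxy];
      dt1d(f.data(), d.data(), nz, spacing[2], z, v);
      for (int k = 0; k < nz; k++) g[off + (R_xlen_t)k * nxy] = d[k];
    }

  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = std::sqrt(g[i]);
  out.attr("dim") = dim;
  return out;
}

// Trilinear interpolation at a world point; voxel centres at
// origin + index * spacing (0-based indices); `outside` beyond the grid.
static inline double trilin(const double* a, int nx, int ny, int nz,
                            const double* sp, const double* org,
                            double px, double py, double pz, double outside) {
  double cx = (px - org[0]) / sp[0];
  double cy = (py - org[1]) / sp[1];
  double cz = (pz - org[2]) / sp[2];
  if (cx < -1.0 || cx > nx || cy < -1.0 || cy > ny || cz < -1.0 || cz > nz)
    return outside;
  int ix = (int)std::floor(cx), iy = (int)std::floor(cy), iz = (int)std::floor(cz);
  double fx = cx - ix, fy = cy - iy, fz = cz - iz;
  double val = 0.0;
  for (int dz = 0; dz < 2; dz++) {
    int z = iz + dz;
    double wz = dz ? fz : 1.0 - fz;
    if (wz == 0.0) continue;
    for (int dy = 0; dy < 2; dy++) {
      int y = iy + dy;
      double wy = dy ? fy : 1.0 - fy;
      if (wy == 0.0) continue;
      for (int dx = 0; dx < 2; dx++) {
        int x = ix + dx;
        double wx = dx ? fx : 1.0 - fx;
        if (wx == 0.0) continue;
        double c;
        if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz)
          c = outside;
        else
          c = a[(R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x];
        val += wx * wy * wz * c;
      }
    }
  }
  return val;
}

// [[Rcpp::export(name = ".trilinear_cpp")]]
NumericVector trilinear_cpp(NumericVector vol, IntegerVector dim,
                            NumericVector spacing, NumericVector origin,
                            NumericMatrix pts, double outside) {
  int n = pts.nrow();
  NumericVector out(n);
  const double* a = REAL(vol);
  for (int i = 0; i < n; i++)
    out[i] = trilin(a, dim[0], dim[1], dim[2], REAL(spacing), REAL(origin),
                    pts(i, 0), pts(i, 1), pts(i, 2), outside);
  return out;
}

// Parallel-beam projection.  For each detector pixel, march along the ray
// p(t) = p0 + t * d with midpoint sampling; mode 0 sums (line integral * step),
// mode 1 takes the max along the ray (silhouette test of a scalar mask).
// [[Rcpp::export(name = ".drr_cpp")]]
NumericMatrix drr_cpp(NumericVector vol, IntegerVector dim,
                      NumericVector spacing, NumericVector origin,
                      NumericVector det_center, NumericVector eu,
                      NumericVector ev, NumericVector dir,
                      int n_u, int n_v, double pixel_spacing,
                      double step, double t0, int nsteps, int mode) {
  NumericMatrix img(n_v, n_u);
  const double* a = REAL(vol);
  const double* sp = REAL(spacing);
  const double* org = REAL(origin);
  double cu = (n_u - 1) / 2.0, cv = (n_v - 1) / 2.0;
  for (int iv = 0; iv < n_v; iv++) {
    for (int iu = 0; iu < n_u; iu++) {
      double u = (iu - cu) * pixel_spacing;
      double v = (iv - cv) * pixel_spacing;
      double px = det_center[0] + u * eu[0] + v * ev[0];
      double py = det_center[1] + u * eu[1] + v * ev[1];
      double pz = det_center[2] + u * eu[2] + v * ev[2];
      double acc = 0.0, mx = 0.0;
      for (int k = 0; k < nsteps; k++) {
        double t = t0 + (k + 0.5) * step;
        double val = trilin(a, dim[0], dim[1], dim[2], sp, org,
                            px + t * dir[0], py + t * dir[1], pz + t * dir[2],
                            0.0);
        if (mode == 0) acc += val; else if (val > mx) mx = val;
      }
      img(iv, iu) = (mode == 0) ? acc * step : mx;
    }
  }
  return img;
}

// Bottleneck-clearance objective on a candidate grid: for every combination of
// start point and direction, the minimum of the (trilinearly sampled) distance
// map over stations t = 0, step, ..., length.  Returns the full objective
// matrix (points x directions) plus the best candidate.
// [[Rcpp::export(name = ".corridor_coarse_cpp")]]
List corridor_coarse_cpp(NumericVector dmap, IntegerVector dim,
                         NumericVector spacing, NumericVector origin,
                         NumericMatrix pts, NumericMatrix dirs,
                         double length, double step) {
  int np = pts.nrow(), nd = dirs.nrow();
  int nst = (int)std::floor(length / step + 1e-9) + 1;
  bool tail = std::fabs((nst - 1) * step - length) > 1e-9;
  const double* a = REAL(dmap);
  const double* sp = REAL(spacing);
  const double* org = REAL(origin);
  NumericMatrix f(np, nd);
  double best = -1.0;
  int bi = 0, bj = 0;
  for (int i = 0; i < np; i++) {
    for (int j = 0; j < nd; j++) {
      double mn = BIG;
      for (int k = 0; k < nst + (tail ? 1 : 0); k++) {
        double t = (k < nst) ? k * step : length;
        double val = trilin(a, dim[0], dim[1], dim[2], sp, org,
                            pts(i, 0) + t * dirs(j, 0),
                            pts(i, 1) + t * dirs(j, 1),
                            pts(i, 2) + t * dirs(j, 2), 0.0);
        if (val < mn) mn = val;
        if (mn <= 0.0) break;
      }
      f(i, j) = mn;
      if (mn > best) { best = mn; bi = i; bj = j; }
    }
  }
  return List::create(_["objective"] = f, _["best_point"] = bi + 1,
                      _["best_dir"] = bj + 1, _["best_value"] = best);
}

// Number of 6-connected foreground components.
// [[Rcpp::export(name = ".n_components_cpp")]]
int n_components_cpp(IntegerVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<char> seen(n, 0);
  int ncomp = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < n; s++) {
    if (!mask[s] || seen[s]) continue;
    ncomp++;
    seen[s] = 1;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t cur = q.front(); q.pop();
      int x = cur % nx, y = (cur / nx) % ny, z = cur / ((R_xlen_t)nx * ny);
      const int off[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (int m = 0; m < 6; m++) {
        int xx = x + off[m][0], yy = y + off[m][1], zz = z + off[m][2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t idx = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
        if (mask[idx] && !seen[idx]) { seen[idx] = 1; q.push(idx); }
      }
    }
  }
  return ncomp;
}
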