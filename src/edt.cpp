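#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

// 1D squared-distance transform (Felzenszwalb & Huttenlocher lower envelope).
// f: squared distances sampled at grid positions 0, w, 2w, ... (w = spacing).
// Entries may be +Inf; at least one entry must be finite.
static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z,
                 int n, double w) {
  const double INF = std::numeric_limits<double>::infinity();
  int q0 = 0;
  while (f[q0] == INF) q0++;
  int k = 0;
  v[0] = q0;
  z[0] = -INF;
  z[1] = +INF;
  for (int q = q0 + 1; q < n; q++) {
    if (f[q] == INF) continue;
    double qq = (double)q * w;
    double s;
    for (;;) {
      double vv = (double)v[k] * w;
      s = ((f[q] + qq * qq) - (f[v[k]] + vv * vv)) / (2 * qq - 2 * vv);
      if (s <= z[k] && k > 0) {
        k--;
      } else if (s <= z[k]) { // k == 0: new parabola dominates everywhere
        v[0] = q;
        s = -INF;
        break;
      } else break;
    }
    if (s == -INF) {
      z[0] = -INF;
      z[1] = +INF;
    } else {
      k++;
      v[k] = q;
      z[k] = s;
      z[k + 1] = +INF;
    }
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    double qq = (double)q * w;
    while (z[k + 1] < qq) k++;
    double vv = (double)v[k] * w;
    d[q] = (qq - vv) * (qq - vv) + f[v[k]];
  }
}

// Exact Euclidean distance transform of a 3D logical array: for every voxel,
// distance (in spacing units) to the nearest TRUE voxel centre.
// [[Rcpp::export(name = ".edt3d_cpp")]]
NumericVector edt3d_cpp(LogicalVector mask, IntegerVector dim,
                        NumericVector spacing) {
  const double INF = std::numeric_limits<double>::infinity();
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> g(n);
  for (R_xlen_t i = 0; i < n; i++)
    g[i] = (mask[i] == TRUE) ? 0.0 : INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++) {
      R_xlen_t off = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
      bool any = false;
      for (int i = 0; i < nx; i++) { f[i] = g[off + i]; if (f[i] < INF) any = true; }
      if (!any) continue;
      dt1d(f, d, v, z, nx, spacing[0]);
      for (int i = 0; i < nx; i++) g[off + i] = d[i];
    }
  // pass along y
  for (int k = 0; k < nz; k++)
    for (int i = 0; i < nx; i++) {
      R_xlen_t off = (R_xlen_t)k * nx * ny + i;
      bool any = false;
      for (int j = 0; j < ny; j++) { f[j] = g[off + (R_xlen_t)j * nx]; if (f[j] < INF) any = true; }
      if (!any) continue;
      dt1d(f, d, v, z, ny, spacing[1]);
      for (int j = 0; j < ny; j++) g[off + (R_xlen_t)j * nx] = d[j];
    }
  // pass along z
  R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; j++)
    for (int i = 0; i < nx; i++) {
      R_xlen_t off = (R_xlen_t)j * nx + i;
      bool any = false;
      for (int k = 0; k < nz; k++) { f[k] = g[off + (R_xlen_t)k * nxy]; if (f[k] < INF) any = true; }
      if (!any) continue;
      dt1d(f, d, v, z, nz, spacing[2]);
      for (int k = 0; k < nz; k++) g[off + (R_xlen_t)k * nxy] = d[k];
    }

  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++)
    out[i] = std::isinf(g[i]) ? R_PosInf : std::sqrt(g[i]);
  out.attr("dim") = dim;
  return out;
}

// 1D pass that also tracks, for every output position, the site (previous
// pass's argmin index) achieving the minimum.
static void dt1d_ft(std::vector<double> &f, std::vector<int> &site,
                    std::vector<double> &d, std::vector<int> &dsite,
                    std::vector<int> &v, std::vector<double> &z,
                    int n, double w) {
  const double INF = std::numeric_limits<double>::infinity();
  int q0 = 0;
  while (f[q0] == INF) q0++;
  int k = 0;
  v[0] = q0;
  z[0] = -INF;
  z[1] = +INF;
  for (int q = q0 + 1; q < n; q++) {
    if (f[q] == INF) continue;
    double qq = (double)q * w;
    double s;
    for (;;) {
      double vv = (double)v[k] * w;
      s = ((f[q] + qq * qq) - (f[v[k]] + vv * vv)) / (2 * qq - 2 * vv);
      if (s <= z[k] && k > 0) {
        k--;
      } else if (s <= z[k]) {
        v[0] = q;
        s = -INF;
        break;
      } else break;
    }
    if (s == -INF) {
      z[0] = -INF;
      z[1] = +INF;
    } else {
      k++;
      v[k] = q;
      z[k] = s;
      z[k + 1] = +INF;
    }
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    double qq = (double)q * w;
    while (z[k + 1] < qq) k++;
    double vv = (double)v[k] * w;
    d[q] = (qq - vv) * (qq - vv) + f[v[k]];
    dsite[q] = site[v[k]];
  }
}

// Euclidean feature transform: for every voxel, the (1-based) linear index
// of the nearest TRUE voxel, plus the distance.
// [[Rcpp::export(name = ".edt3d_ft_cpp")]]
List edt3d_ft_cpp(LogicalVector mask, IntegerVector dim,
                  NumericVector spacing) {
  const double INF = std::numeric_limits<double>::infinity();
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> g(n);
  std::vector<int> src(n);
  for (R_xlen_t i = 0; i < n; i++) {
    bool in = (mask[i] == TRUE);
    g[i] = in ? 0.0 : INF;
    src[i] = in ? (int)(i + 1) : 0;
  }
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax), st(nmax), dst(nmax);

  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++) {
      R_xlen_t off = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
      bool any = false;
      for (int i = 0; i < nx; i++) {
        f[i] = g[off + i]; st[i] = src[off + i];
        if (f[i] < INF) any = true;
      }
      if (!any) continue;
      dt1d_ft(f, st, d, dst, v, z, nx, spacing[0]);
      for (int i = 0; i < nx; i++) { g[off + i] = d[i]; src[off + i] = dst[i]; }
    }
  for (int k = 0; k < nz; k++)
    for (int i = 0; i < nx; i++) {
      R_xlen_t off = (R_xlen_t)k * nx * ny + i;
      bool any = false;
      for (int j = 0; j < ny; j++) {
        f[j] = g[off + (R_xlen_t)j * nx]; st[j] = src[off + (R_xlen_t)j * nx];
        if (f[j] < INF) any = true;
      }
      if (!any) continue;
      dt1d_ft(f, st, d, dst, v, z, ny, spacing[1]);
      for (int j = 0; j < ny; j++) {
        g[off + (R_xlen_t)j * nx] = d[j]; src[off + (R_xlen_t)j * nx] = dst[j];
      }
    }
  R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; j++)
    for (int i = 0; i < nx; i++) {
      R_xlen_t off = (R_xlen_t)j * nx + i;
      bool any = false;
      for (int k = 0; k < nz; k++) {
        f[k] = g[off + (R_xlen_t)k * nxy]; st[k] = src[off + (R_xlen_t)k * nxy];
        if (f[k] < INF) any = true;
      }
      if (!any) continue;
      dt1d_ft(f, st, d, dst, v, z, nz, spacing[2]);
      for (int k = 0; k < nz; k++) {
        g[off + (R_xlen_t)k * nxy] = d[k]; src[off + (R_xlen_t)k * nxy] = dst[k];
      }
    }
  NumericVector dist(n);
  IntegerVector idx(n);
  for (R_xlen_t i = 0; i < n; i++) {
    dist[i] = std::isinf(g[i]) ? R_PosInf : std::sqrt(g[i]);
    idx[i] = src[i];
  }
  dist.attr("dim") = dim;
  idx.attr("dim") = dim;
  return List::create(_["distance"] = dist, _["index"] = idx);
}
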