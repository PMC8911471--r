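#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// 1-D squared-distance transform (lower envelope of parabolas) with sample
// spacing h.  f holds squared distances at positions i*h; d receives the
// transformed values.  Felzenszwalb & Huttenlocher, Theory of Computing 2012.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z,
                 int n, double h) {
  // Parabolas with infinite height never enter the lower envelope, so a
  // line with no finite sample stays infinite and mixed lines are handled
  // without special cases.
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (!(f[q] < INF)) continue;
    double xq = q * h;
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -INF; z[1] = INF;
      continue;
    }
    double s = 0.0;
    while (k >= 0) {
      double xv = v[k] * h;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * (xq - xv));
      if (s <= z[k]) --k; else break;
    }
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -INF; z[1] = INF;
    } else {
      ++k; v[k] = q; z[k] = s; z[k + 1] = INF;
    }
  }
  if (k < 0) {
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * h;
    while (z[k + 1] < xq) ++k;
    double xv = v[k] * h;
    d[q] = (xq - xv) * (xq - xv) + f[v[k]];
  }
}

// [[Rcpp::export(name = ".edt_sq")]]
NumericVector edt_sq(LogicalVector mask, IntegerVector dim,
                     NumericVector spacing) {
  if (dim.size() != 3 || spacing.size() != 3)
    stop("dim and spacing must have length 3");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dim");

  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = (mask[i] == TRUE) ? 0.0 : INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // along x (fastest-varying index)
  for (int kzi = 0; kzi < nz; ++kzi) {
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)kzi * nx * ny + (R_xlen_t)j * nx;
      for (int i = 0; i < nx; ++i) f[i] = out[base + i];
      dt1d(f, d, v, z, nx, spacing[0]);
      for (int i = 0; i < nx; ++i) out[base + i] = d[i];
    }
  }
  // along y
  for (int kzi = 0; kzi < nz; ++kzi) {
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)kzi * nx * ny + i;
      for (int j = 0; j < ny; ++j) f[j] = out[base + (R_xlen_t)j * nx];
      dt1d(f, d, v, z, ny, spacing[1]);
      for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)j * nx] = d[j];
    }
  }
  // along z
  const R_xlen_t slab = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)j * nx + i;
      for (int kzi = 0; kzi < nz; ++kzi) f[kzi] = out[base + kzi * slab];
      dt1d(f, d, v, z, nz, spacing[2]);
      for (int kzi = 0; kzi < nz; ++kzi) out[base + kzi * slab] = d[kzi];
    }
  }
  return out;
}
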