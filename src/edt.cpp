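#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

// 1-D squared Euclidean distance transform (lower envelope of parabolas),
// Felzenszwalb & Huttenlocher (2012). f holds squared distances; w is the
// voxel size along this axis.
static void dt1d(std::vector<double> &f, double w) {
  const int n = f.size();
  if (n == 0) return;
  std::vector<double> d(n), z(n + 1);
  std::vector<int> v(n);
  const double inf = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -inf;
  z[1] = inf;
  const double w2 = w * w;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
          (2.0 * w2 * (q - v[k]));
      if (s <= z[k]) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = inf;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = w * (q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
  f = d;
}

// Exact Euclidean distance (mm) from every voxel to the nearest TRUE voxel.
// mask: logical array, dim: its dimensions, voxdim: voxel sizes in mm.
// [[Rcpp::export(name = ".edt3d")]]
NumericVector edt3d(LogicalVector mask, IntegerVector dim, NumericVector voxdim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  // large finite sentinel keeps the parabola intersections finite
  const double big = 1e20;
  NumericVector out(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i)
    out[i] = (mask[i] == TRUE) ? 0.0 : big;

  std::vector<double> buf;
  // pass along x
  buf.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      const R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
      for (int x = 0; x < nx; ++x) buf[x] = out[base + x];
      dt1d(buf, voxdim[0]);
      for (int x = 0; x < nx; ++x) out[base + x] = buf[x];
    }
  // pass along y
  buf.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      const R_xlen_t base = (R_xlen_t)z * nx * ny + x;
      for (int y = 0; y < ny; ++y) buf[y] = out[base + (R_xlen_t)y * nx];
      dt1d(buf, voxdim[1]);
      for (int y = 0; y < ny; ++y) out[base + (R_xlen_t)y * nx] = buf[y];
    }
  // pass along z
  buf.resize(nz);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      const R_xlen_t base = (R_xlen_t)y * nx + x;
      for (int z = 0; z < nz; ++z) buf[z] = out[base + (R_xlen_t)z * nx * ny];
      dt1d(buf, voxdim[2]);
      for (int z = 0; z < nz; ++z) out[base + (R_xlen_t)z * nx * ny] = buf[z];
    }
  for (R_xlen_t i = 0; i < out.size(); ++i) out[i] = std::sqrt(out[i]);
  out.attr("dim") = dim;
  return out;
}
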