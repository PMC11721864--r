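#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>

// Exact Euclidean distance transform on a 3D grid with anisotropic spacing,
// via the separable lower-envelope algorithm (Felzenszwalb & Huttenlocher).
// Distances are between voxel centers, in the units of `spacing`.

static const double INF = std::numeric_limits<double>::infinity();

// One 1D pass over squared distances. f/d have n entries at stride `stride`.
// w2 is the squared grid step along this axis.
static void dt1d(const double* f, double* d, int n, int stride, double w2,
                 std::vector<int>& v, std::vector<double>& z) {
  int k = -1;
  for (int q = 0; q < n; q++) {
    double fq = f[q * stride];
    if (fq == INF) continue;
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -INF; z[1] = INF;
      continue;
    }
    double s = ((fq + w2 * q * q) - (f[v[k] * stride] + w2 * v[k] * v[k])) /
               (2.0 * w2 * (q - v[k]));
    while (s <= z[k]) {
      k--;
      s = ((fq + w2 * q * q) - (f[v[k] * stride] + w2 * v[k] * v[k])) /
          (2.0 * w2 * (q - v[k]));
    }
    k++; v[k] = q; z[k] = s; z[k + 1] = INF;
  }
  if (k < 0) { // whole line at infinity
    for (int q = 0; q < n; q++) d[q * stride] = INF;
    return;
  }
  int j = 0;
  for (int q = 0; q < n; q++) {
    while (z[j + 1] < q) j++;
    double dq = q - v[j];
    d[q * stride] = w2 * dq * dq + f[v[j] * stride];
  }
}

// [[Rcpp::export(name = ".edt3d_cpp")]]
Rcpp::NumericVector edt3d_cpp(Rcpp::LogicalVector mask,
                              Rcpp::IntegerVector dims,
                              Rcpp::NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) Rcpp::stop("mask length does not match dims");
  std::vector<double> f(n), g(n);
  for (R_xlen_t i = 0; i < n; i++) f[i] = (mask[i] == TRUE) ? 0.0 : INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<int> v(nmax);
  std::vector<double> z(nmax + 1);

  const double wx2 = spacing[0] * spacing[0];
  const double wy2 = spacing[1] * spacing[1];
  const double wz2 = spacing[2] * spacing[2];

  // axis 0 (stride 1), f -> g
  for (int kz = 0; kz < nz; kz++)
    for (int jy = 0; jy < ny; jy++) {
      R_xlen_t off = (R_xlen_t)nx * (jy + (R_xlen_t)ny * kz);
      dt1d(&f[off], &g[off], nx, 1, wx2, v, z);
    }
  // axis 1 (stride nx), g -> f
  for (int kz = 0; kz < nz; kz++)
    for (int ix = 0; ix < nx; ix++) {
      R_xlen_t off = ix + (R_xlen_t)nx * ny * kz;
      dt1d(&g[off], &f[off], ny, nx, wy2, v, z);
    }
  // axis 2 (stride nx*ny), f -> g
  for (int jy = 0; jy < ny; jy++)
    for (int ix = 0; ix < nx; ix++) {
      R_xlen_t off = ix + (R_xlen_t)nx * jy;
      dt1d(&f[off], &g[off], nz, nx * ny, wz2, v, z);
    }

  Rcpp::NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = std::sqrt(g[i]);
  out.attr("dim") = dims;
  return out;
}
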