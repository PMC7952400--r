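#include <Rcpp.h>
#include <queue>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Volumes are R arrays: x fastest, 0-based linear index i + nx*(j + ny*k).
static inline int lin(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + (long long)ny * k);
}

// Trilinear interpolation at continuous 0-based voxel coordinates.
// Returns value and (optionally) the exact gradient of the interpolant
// with respect to the coordinate (per voxel unit).
static bool trilerp(const double* v, int nx, int ny, int nz,
                    double x, double y, double z,
                    double& val, double* grad) {
  if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1)
    return false;
  int i = (int)std::floor(x), j = (int)std::floor(y), k = (int)std::floor(z);
  if (i == nx - 1) i--;
  if (j == ny - 1) j--;
  if (k == nz - 1) k--;
  double fx = x - i, fy = y - j, fz = z - k;
  double c[2][2][2];
  for (int dk = 0; dk < 2; dk++)
    for (int dj = 0; dj < 2; dj++)
      for (int di = 0; di < 2; di++)
        c[di][dj][dk] = v[lin(i + di, j + dj, k + dk, nx, ny)];
  double wx[2] = {1 - fx, fx}, wy[2] = {1 - fy, fy}, wz[2] = {1 - fz, fz};
  val = 0.0;
  double gx = 0.0, gy = 0.0, gz = 0.0;
  for (int dk = 0; dk < 2; dk++)
    for (int dj = 0; dj < 2; dj++)
      for (int di = 0; di < 2; di++) {
        double cv = c[di][dj][dk];
        val += cv * wx[di] * wy[dj] * wz[dk];
        if (grad) {
          gx += cv * (di ? 1.0 : -1.0) * wy[dj] * wz[dk];
          gy += cv * wx[di] * (dj ? 1.0 : -1.0) * wz[dk];
          gz += cv * wx[di] * wy[dj] * (dk ? 1.0 : -1.0);
        }
      }
  if (grad) { grad[0] = gx; grad[1] = gy; grad[2] = gz; }
  return true;
}

// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector vol, IntegerVector dim,
                            NumericMatrix pts) {
  int nx = dim[0], ny = dim[1], nz = dim[2], n = pts.nrow();
  NumericVector out(n);
  const double* v = vol.begin();
  for (int a = 0; a < n; a++) {
    double val;
    if (trilerp(v, nx, ny, nz, pts(a, 0), pts(a, 1), pts(a, 2), val, nullptr))
      out[a] = val;
    else
      out[a] = NA_REAL;
  }
  return out;
}

// Sample a 3-component field stored as (nx,ny,nz,3) at continuous voxel coords.
// [[Rcpp::export]]
NumericMatrix cpp_trilinear_field(NumericVector fld, IntegerVector dim,
                                  NumericMatrix pts) {
  int nx = dim[0], ny = dim[1], nz = dim[2], n = pts.nrow();
  long long nvox = (long long)nx * ny * nz;
  NumericMatrix out(n, 3);
  for (int comp = 0; comp < 3; comp++) {
    const double* v = fld.begin() + comp * nvox;
    for (int a = 0; a < n; a++) {
      double val;
      if (trilerp(v, nx, ny, nz, pts(a, 0), pts(a, 1), pts(a, 2), val, nullptr))
        out(a, comp) = val;
      else
        out(a, comp) = NA_REAL;
    }
  }
  return out;
}

// Separable Gaussian blur, sigma in voxels, truncated at 3 sigma,
// renormalised at the borders.
// [[Rcpp::export]]
NumericVector cpp_gaussian_blur(NumericVector vol, IntegerVector dim,
                                double sigma) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long long nvox = (long long)nx * ny * nz;
  if (sigma <= 0) return clone(vol);
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> ker(2 * r + 1);
  for (int t = -r; t <= r; t++) ker[t + r] = std::exp(-0.5 * t * t / (sigma * sigma));
  std::vector<double> a(vol.begin(), vol.end()), b(nvox);
  int n[3] = {nx, ny, nz};
  long long stride[3] = {1, nx, (long long)nx * ny};
  for (int ax = 0; ax < 3; ax++) {
    int len = n[ax];
    long long st = stride[ax];
    for (long long base = 0; base < nvox; base++) {
      // walk only the lines once: base must have coordinate 0 along ax
      long long coord = (base / st) % len;
      if (coord != 0) continue;
      for (int p = 0; p < len; p++) {
        double s = 0, w = 0;
        int lo = std::max(0, p - r), hi = std::min(len - 1, p + r);
        for (int q = lo; q <= hi; q++) {
          double kk = ker[q - p + r];
          s += kk * a[base + (long long)q * st];
          w += kk;
        }
        b[base + (long long)p * st] = s / w;
      }
    }
    a.swap(b);
  }
  return NumericVector(a.begin(), a.end());
}

// Block-mean downsample by an integer factor per axis.
// [[Rcpp::export]]
NumericVector cpp_downsample(NumericVector vol, IntegerVector dim,
                             IntegerVector factor) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int fx = factor[0], fy = factor[1], fz = factor[2];
  int mx = nx / fx, my = ny / fy, mz = nz / fz;
  NumericVector out(Dimension(mx, my, mz));
  const double* v = vol.begin();
  for (int k = 0; k < mz; k++)
    for (int j = 0; j < my; j++)
      for (int i = 0; i < mx; i++) {
        double s = 0;
        for (int dk = 0; dk < fz; dk++)
          for (int dj = 0; dj < fy; dj++)
            for (int di = 0; di < fx; di++)
              s += v[lin(i * fx + di, j * fy + dj, k * fz + dk, nx, ny)];
        out[lin(i, j, k, mx, my)] = s / (fx * fy * fz);
      }
  return out;
}

// 6-connected flood fill from seed voxels, keeping intensities in [lo, hi].
// Seeds are 0-based voxel indices (n x 3).
// [[Rcpp::export]]
LogicalVector cpp_region_grow(NumericVector vol, IntegerVector dim,
                              IntegerMatrix seeds, double lo, double hi) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long long nvox = (long long)nx * ny * nz;
  std::vector<char> mask(nvox, 0);
  std::queue<long long> q;
  const double* v = vol.begin();
  for (int s = 0; s < seeds.nrow(); s++) {
    long long id = lin(seeds(s, 0), seeds(s, 1), seeds(s, 2), nx, ny);
    if (v[id] >= lo && v[id] <= hi && !mask[id]) { mask[id] = 1; q.push(id); }
  }
  const int dx[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, 1, -1};
  while (!q.empty()) {
    long long id = q.front(); q.pop();
    int i = id % nx, j = (id / nx) % ny, k = id / ((long long)nx * ny);
    for (int d = 0; d < 6; d++) {
      int ii = i + dx[d], jj = j + dy[d], kk = k + dz[d];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
      long long nid = lin(ii, jj, kk, nx, ny);
      if (!mask[nid] && v[nid] >= lo && v[nid] <= hi) { mask[nid] = 1; q.push(nid); }
    }
  }
  LogicalVector out(nvox);
  for (long long t = 0; t < nvox; t++) out[t] = mask[t] != 0;
  out.attr("dim") = dim;
  return out;
}

// Felzenszwalb-Huttenlocher 1D squared distance transform.
static void dt1d(const double* f, double* d, int n, double w2) {
  std::vector<int> vvx(n);
  std::vector<double> zz(n + 1);
  int k = 0;
  vvx[0] = 0;
  zz[0] = -std::numeric_limits<double>::infinity();
  zz[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; q++) {
    double s;
    while (true) {
      int p = vvx[k];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w2 * (q - p));
      if (s <= zz[k]) { k--; } else break;
    }
    k++;
    vvx[k] = q; zz[k] = s; zz[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (zz[k + 1] < q) k++;
    int p = vvx[k];
    d[q] = w2 * (q - p) * (q - p) + f[p];
  }
}

// Exact Euclidean distance (mm) to the nearest TRUE voxel centre.
// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector dim,
                      NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long long nvox = (long long)nx * ny * nz;
  const double INF = 1e30;
  std::vector<double> d(nvox);
  for (long long t = 0; t < nvox; t++) d[t] = mask[t] ? 0.0 : INF;
  int n[3] = {nx, ny, nz};
  long long stride[3] = {1, nx, (long long)nx * ny};
  std::vector<double> f, g;
  for (int ax = 0; ax < 3; ax++) {
    int len = n[ax];
    long long st = stride[ax];
    double w2 = spacing[ax] * spacing[ax];
    f.resize(len); g.resize(len);
    for (long long base = 0; base < nvox; base++) {
      long long coord = (base / st) % len;
      if (coord != 0) continue;
      for (int p = 0; p < len; p++) f[p] = d[base + (long long)p * st];
      dt1d(f.data(), g.data(), len, w2);
      for (int p = 0; p < len; p++) d[base + (long long)p * st] = g[p];
    }
  }
  NumericVector out(nvox);
  for (long long t = 0; t < nvox; t++) out[t] = std::sqrt(d[t]);
  out.attr("dim") = dim;
  return out;
}
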