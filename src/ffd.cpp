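#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Cubic uniform B-spline basis and first derivative.
static inline void bspl(double u, double* w) {
  double v = 1.0 - u;
  w[0] = v * v * v / 6.0;
  w[1] = (3.0 * u * u * u - 6.0 * u * u + 4.0) / 6.0;
  w[2] = (-3.0 * u * u * u + 3.0 * u * u + 3.0 * u + 1.0) / 6.0;
  w[3] = u * u * u / 6.0;
}

static inline int lin(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + (long long)ny * k);
}

// Trilinear value with the exact interpolant gradient. The interpolant is
// non-differentiable exactly on lattice planes; there the one-sided cell
// derivative is replaced by the average of the two adjacent cells' (a
// central difference), which removes the systematic bias a zero-initialised
// transform would otherwise see while leaving the gradient unchanged at
// every off-lattice point.
static bool trilerp_g(const double* v, int nx, int ny, int nz,
                      double x, double y, double z,
                      double& val, double* grad) {
  if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1)
    return false;
  int i = (int)std::floor(x), j = (int)std::floor(y), k = (int)std::floor(z);
  if (i == nx - 1) i--;
  if (j == ny - 1) j--;
  if (k == nz - 1) k--;
  double fx = x - i, fy = y - j, fz = z - k;
  double wx[2] = {1 - fx, fx}, wy[2] = {1 - fy, fy}, wz[2] = {1 - fz, fz};
  val = 0; grad[0] = grad[1] = grad[2] = 0;
  for (int dk = 0; dk < 2; dk++)
    for (int dj = 0; dj < 2; dj++)
      for (int di = 0; di < 2; di++) {
        double cv = v[lin(i + di, j + dj, k + dk, nx, ny)];
        val += cv * wx[di] * wy[dj] * wz[dk];
        grad[0] += cv * (di ? 1.0 : -1.0) * wy[dj] * wz[dk];
        grad[1] += cv * wx[di] * (dj ? 1.0 : -1.0) * wz[dk];
        grad[2] += cv * wx[di] * wy[dj] * (dk ? 1.0 : -1.0);
      }
  const double frac[3] = {fx, fy, fz};
  const int idx[3] = {i, j, k};
  for (int ax = 0; ax < 3; ax++) {
    if (frac[ax] != 0.0 || idx[ax] <= 0) continue;
    // on a lattice plane: derivative along ax from the left cell, with the
    // in-plane weights of the other two axes
    double gl = 0;
    for (int dk = 0; dk < 2; dk++)
      for (int dj = 0; dj < 2; dj++) {
        int o1 = (ax == 0) ? 1 : 0;            // first other axis
        int o2 = (ax == 2) ? 1 : 2;            // second other axis
        int c[3];
        c[ax] = idx[ax];                        // right face of left cell
        c[o1] = idx[o1] + dj;
        c[o2] = idx[o2] + dk;
        double w = ((o1 == 0) ? wx[dj] : wy[dj]) *
                   ((o2 == 1) ? wy[dk] : wz[dk]);
        double hi = v[lin(c[0], c[1], c[2], nx, ny)];
        c[ax] = idx[ax] - 1;
        double lo = v[lin(c[0], c[1], c[2], nx, ny)];
        gl += w * (hi - lo);
      }
    grad[ax] = 0.5 * (grad[ax] + gl);
  }
  return true;
}

// Evaluate the B-spline displacement at world points.
// phi: (ncx,ncy,ncz,3) control displacements (mm); grid origin/spacing in mm.
// Points outside the spline support get NA.
// [[Rcpp::export]]
NumericMatrix cpp_ffd_evaluate(NumericVector phi, IntegerVector nc,
                               NumericVector gorigin, NumericVector gspacing,
                               NumericMatrix pts) {
  int ncx = nc[0], ncy = nc[1], ncz = nc[2], n = pts.nrow();
  long long ncp = (long long)ncx * ncy * ncz;
  NumericMatrix out(n, 3);
  const double* ph = phi.begin();
  for (int a = 0; a < n; a++) {
    double g[3], wx[4], wy[4], wz[4];
    int ib[3];
    bool ok = true;
    for (int ax = 0; ax < 3; ax++) {
      g[ax] = (pts(a, ax) - gorigin[ax]) / gspacing[ax];
      int i = (int)std::floor(g[ax]);
      if (i - 1 < 0 || i + 2 > nc[ax] - 1) { ok = false; break; }
      ib[ax] = i;
    }
    if (!ok) {
      out(a, 0) = out(a, 1) = out(a, 2) = NA_REAL;
      continue;
    }
    bspl(g[0] - ib[0], wx); bspl(g[1] - ib[1], wy); bspl(g[2] - ib[2], wz);
    double acc[3] = {0, 0, 0};
    for (int dk = 0; dk < 4; dk++)
      for (int dj = 0; dj < 4; dj++)
        for (int di = 0; di < 4; di++) {
          double w = wx[di] * wy[dj] * wz[dk];
          long long id = lin(ib[0] - 1 + di, ib[1] - 1 + dj, ib[2] - 1 + dk,
                             ncx, ncy);
          for (int c = 0; c < 3; c++) acc[c] += w * ph[id + c * ncp];
        }
    for (int c = 0; c < 3; c++) out(a, c) = acc[c];
  }
  return out;
}

struct AxisTab {
  std::vector<int> base;      // first control index (i-1)
  std::vector<double> w;      // 4 weights per sample
  std::vector<char> ok;
};

static AxisTab axis_table(int nvox, double iorig, double ispc,
                          double gorig, double gspc, int ncpts) {
  AxisTab t;
  t.base.resize(nvox); t.w.resize(4 * nvox); t.ok.resize(nvox);
  for (int p = 0; p < nvox; p++) {
    double g = (iorig + p * ispc - gorig) / gspc;
    int i = (int)std::floor(g);
    if (i - 1 < 0 || i + 2 > ncpts - 1) { t.ok[p] = 0; continue; }
    t.ok[p] = 1;
    t.base[p] = i - 1;
    bspl(g - i, &t.w[4 * p]);
  }
  return t;
}

// Rasterise the spline displacement on an image lattice -> (nx,ny,nz,3).
// [[Rcpp::export]]
NumericVector cpp_ffd_rasterise(NumericVector phi, IntegerVector nc,
                                NumericVector gorigin, NumericVector gspacing,
                                IntegerVector idim, NumericVector iorigin,
                                NumericVector ispacing) {
  int nx = idim[0], ny = idim[1], nz = idim[2];
  int ncx = nc[0], ncy = nc[1];
  long long ncp = (long long)nc[0] * nc[1] * nc[2];
  long long nvox = (long long)nx * ny * nz;
  AxisTab tx = axis_table(nx, iorigin[0], ispacing[0], gorigin[0], gspacing[0], nc[0]);
  AxisTab ty = axis_table(ny, iorigin[1], ispacing[1], gorigin[1], gspacing[1], nc[1]);
  AxisTab tz = axis_table(nz, iorigin[2], ispacing[2], gorigin[2], gspacing[2], nc[2]);
  NumericVector out((R_xlen_t)(3 * nvox));
  out.attr("dim") = IntegerVector::create(nx, ny, nz, 3);
  const double* ph = phi.begin();
  double* o = out.begin();
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        long long vid = lin(i, j, k, nx, ny);
        if (!tx.ok[i] || !ty.ok[j] || !tz.ok[k]) {
          o[vid] = o[vid + nvox] = o[vid + 2 * nvox] = NA_REAL;
          continue;
        }
        double acc[3] = {0, 0, 0};
        for (int dk = 0; dk < 4; dk++)
          for (int dj = 0; dj < 4; dj++) {
            double wjk = ty.w[4 * j + dj] * tz.w[4 * k + dk];
            long long rowid = lin(tx.base[i], ty.base[j] + dj, tz.base[k] + dk,
                                  ncx, ncy);
            for (int di = 0; di < 4; di++) {
              double w = tx.w[4 * i + di] * wjk;
              for (int c = 0; c < 3; c++) acc[c] += w * ph[rowid + di + c * ncp];
            }
          }
        for (int c = 0; c < 3; c++) o[vid + c * nvox] = acc[c];
      }
  return out;
}

// Mean SSD between ref and the warped target plus its exact gradient with
// respect to the control-point displacements. Warped intensity is the
// trilinear interpolant of tgt at x + base(x) + h(x), where base is an
// optional frozen displacement (mm) from previous transform levels sampled
// on the image lattice (length 3*nvox, or empty). Out-of-bounds samples are
// excluded from the mean.
// [[Rcpp::export]]
List cpp_ffd_objective(NumericVector ref, NumericVector tgt, IntegerVector idim,
                       NumericVector iorigin, NumericVector ispacing,
                       NumericVector phi, IntegerVector nc,
                       NumericVector gorigin, NumericVector gspacing,
                       bool want_grad, NumericVector base) {
  int nx = idim[0], ny = idim[1], nz = idim[2];
  long long nvox = (long long)nx * ny * nz;
  bool has_base = base.size() == 3 * nvox;
  const double* bs = has_base ? base.begin() : nullptr;
  int ncx = nc[0], ncy = nc[1];
  long long ncp = (long long)nc[0] * nc[1] * nc[2];
  AxisTab tx = axis_table(nx, iorigin[0], ispacing[0], gorigin[0], gspacing[0], nc[0]);
  AxisTab ty = axis_table(ny, iorigin[1], ispacing[1], gorigin[1], gspacing[1], nc[1]);
  AxisTab tz = axis_table(nz, iorigin[2], ispacing[2], gorigin[2], gspacing[2], nc[2]);
  const double* ph = phi.begin();
  const double* rv = ref.begin();
  const double* tv = tgt.begin();
  NumericVector grad((R_xlen_t)(3 * ncp));
  grad.attr("dim") = IntegerVector::create(nc[0], nc[1], nc[2], 3);
  double* gr = grad.begin();
  double ssd = 0.0;
  long long nin = 0;
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        if (!tx.ok[i] || !ty.ok[j] || !tz.ok[k]) continue;
        double h[3] = {0, 0, 0};
        for (int dk = 0; dk < 4; dk++)
          for (int dj = 0; dj < 4; dj++) {
            double wjk = ty.w[4 * j + dj] * tz.w[4 * k + dk];
            long long rowid = lin(tx.base[i], ty.base[j] + dj, tz.base[k] + dk,
                                  ncx, ncy);
            for (int di = 0; di < 4; di++) {
              double w = tx.w[4 * i + di] * wjk;
              for (int c = 0; c < 3; c++) h[c] += w * ph[rowid + di + c * ncp];
            }
          }
        long long vid0 = lin(i, j, k, nx, ny);
        if (has_base) {
          h[0] += bs[vid0];
          h[1] += bs[vid0 + nvox];
          h[2] += bs[vid0 + 2 * nvox];
        }
        // warped sample position in voxel units of tgt
        double sx = i + h[0] / ispacing[0];
        double sy = j + h[1] / ispacing[1];
        double sz = k + h[2] / ispacing[2];
        double val, g[3];
        if (!trilerp_g(tv, nx, ny, nz, sx, sy, sz, val, g)) continue;
        double e = rv[lin(i, j, k, nx, ny)] - val;
        ssd += e * e;
        nin++;
        if (!want_grad) continue;
        // d(e^2)/dh_c = -2 e * dval/dh_c ; dval/dh_c = g[c] / ispacing[c]
        double dh[3];
        for (int c = 0; c < 3; c++) dh[c] = -2.0 * e * g[c] / ispacing[c];
        for (int dk = 0; dk < 4; dk++)
          for (int dj = 0; dj < 4; dj++) {
            double wjk = ty.w[4 * j + dj] * tz.w[4 * k + dk];
            long long rowid = lin(tx.base[i], ty.base[j] + dj, tz.base[k] + dk,
                                  ncx, ncy);
            for (int di = 0; di < 4; di++) {
              double w = tx.w[4 * i + di] * wjk;
              for (int c = 0; c < 3; c++)
                gr[rowid + di + c * ncp] += w * dh[c];
            }
          }
      }
  if (nin == 0) stop("no in-bounds samples");
  for (long long t = 0; t < 3 * ncp; t++) gr[t] /= (double)nin;
  return List::create(_["value"] = ssd / (double)nin, _["grad"] = grad,
                      _["n"] = (double)nin);
}
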