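#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline long long lin(int i, int j, int k, int nx, int ny) {
  return i + (long long)nx * (j + (long long)ny * k);
}

// Binarised self-similarity context descriptors. For each voxel the
// Gaussian-weighted patch SSD is computed between the 12 orthogonal pairs of
// the six unit-offset neighbours; SSDs are turned into self-similarities by
// exp(-ssd / sigma2) with sigma2 the per-voxel mean SSD (which makes the
// descriptor invariant to affine intensity rescaling), then each channel is
// binarised against the voxel's mean channel value (ties -> 0). Returns an
// integer volume of 12-bit codes; border voxels (no full patch support) are 0.
// [[Rcpp::export]]
IntegerVector cpp_ssc(NumericVector vol, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  const double* v = vol.begin();
  const int OFF[6][3] = {
    {1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}
  };
  // 12 orthogonal (non-opposite) unordered pairs
  int pr[12][2], np = 0;
  for (int a = 0; a < 6; a++)
    for (int b = a + 1; b < 6; b++) {
      int dp = OFF[a][0]*OFF[b][0] + OFF[a][1]*OFF[b][1] + OFF[a][2]*OFF[b][2];
      if (dp == 0) { pr[np][0] = a; pr[np][1] = b; np++; }
    }
  // Gaussian patch weights, 3x3x3, sigma 0.8 voxels
  double w[27]; int woff[27][3]; int nw = 0; double wsum = 0;
  for (int dz = -1; dz <= 1; dz++)
    for (int dy = -1; dy <= 1; dy++)
      for (int dx = -1; dx <= 1; dx++) {
        double g = std::exp(-(dx*dx + dy*dy + dz*dz) / (2.0 * 0.8 * 0.8));
        w[nw] = g; woff[nw][0] = dx; woff[nw][1] = dy; woff[nw][2] = dz;
        wsum += g; nw++;
      }
  for (int t = 0; t < nw; t++) w[t] /= wsum;
  IntegerVector out(Dimension(nx, ny, nz));
  int* o = out.begin();
  // support: patch (1) + offset (1) = 2 voxels margin
  for (int k = 2; k < nz - 2; k++)
    for (int j = 2; j < ny - 2; j++)
      for (int i = 2; i < nx - 2; i++) {
        double ssd[12], mssd = 0;
        for (int p = 0; p < 12; p++) {
          int ax = OFF[pr[p][0]][0], ay = OFF[pr[p][0]][1], az = OFF[pr[p][0]][2];
          int bx = OFF[pr[p][1]][0], by = OFF[pr[p][1]][1], bz = OFF[pr[p][1]][2];
          double s = 0;
          for (int t = 0; t < nw; t++) {
            double da = v[lin(i + ax + woff[t][0], j + ay + woff[t][1],
                              k + az + woff[t][2], nx, ny)];
            double db = v[lin(i + bx + woff[t][0], j + by + woff[t][1],
                              k + bz + woff[t][2], nx, ny)];
            s += w[t] * (da - db) * (da - db);
          }
          ssd[p] = s;
          mssd += s / 12.0;
        }
        double sim[12], msim = 0;
        for (int p = 0; p < 12; p++) {
          sim[p] = (mssd > 0) ? std::exp(-ssd[p] / mssd) : 1.0;
          msim += sim[p] / 12.0;
        }
        int code = 0;
        for (int p = 0; p < 12; p++)
          if (sim[p] > msim) code |= (1 << p);
        o[lin(i, j, k, nx, ny)] = code;
      }
  return out;
}

// Unary label costs: mean Hamming distance (bits) between reference
// descriptors in a patch around each control point and target descriptors
// around the displaced position. Labels taking any patch sample out of
// bounds cost +Inf.
// cps: n x 3 0-based voxel indices in the reference; tgt_base: n x 3 voxel
// positions in the target around which labels are searched (equals cps for
// the first level, cps + current displacement on later levels);
// labels: L x 3 voxel offsets.
// [[Rcpp::export]]
NumericMatrix cpp_unary_costs(IntegerVector dref, IntegerVector dtgt,
                              IntegerVector dim, IntegerMatrix cps,
                              IntegerMatrix tgt_base, IntegerMatrix labels,
                              int hw, int step) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = cps.nrow(), L = labels.nrow();
  const int* a = dref.begin();
  const int* b = dtgt.begin();
  NumericMatrix out(n, L);
  std::vector<int> poff;
  for (int dz = -hw; dz <= hw; dz += step)
    for (int dy = -hw; dy <= hw; dy += step)
      for (int dx = -hw; dx <= hw; dx += step) {
        poff.push_back(dx); poff.push_back(dy); poff.push_back(dz);
      }
  int npp = (int)poff.size() / 3;
  for (int p = 0; p < n; p++) {
    int ci = cps(p, 0), cj = cps(p, 1), ck = cps(p, 2);
    int bi = tgt_base(p, 0), bj = tgt_base(p, 1), bk = tgt_base(p, 2);
    for (int l = 0; l < L; l++) {
      int ui = labels(l, 0) + bi - ci, uj = labels(l, 1) + bj - cj,
          uk = labels(l, 2) + bk - ck;
      double acc = 0;
      bool ok = true;
      for (int t = 0; t < npp; t++) {
        int ri = ci + poff[3*t], rj = cj + poff[3*t+1], rk = ck + poff[3*t+2];
        int ti = ri + ui, tj = rj + uj, tk = rk + uk;
        if (ri < 0 || rj < 0 || rk < 0 || ri >= nx || rj >= ny || rk >= nz ||
            ti < 0 || tj < 0 || tk < 0 || ti >= nx || tj >= ny || tk >= nz) {
          ok = false; break;
        }
        int x = a[lin(ri, rj, rk, nx, ny)] ^ b[lin(ti, tj, tk, nx, ny)];
        acc += __builtin_popcount((unsigned)x);
      }
      out(p, l) = ok ? acc / npp : R_PosInf;
    }
  }
  return out;
}

// Exact min-sum (belief propagation) on a tree for the labeling problem
//   min sum_p cost(p, f_p) + theta * sum_{(p,parent(p))} ||u_{f_p}-u_{f_q}||^2.
// parent: 1-based parent index per node, NA/0 for the root.
// order: 1-based node indices, root first, parents before children.
// labels: L x 3 displacement coordinates (units arbitrary, squared Euclidean).
// Returns 1-based label index per node and the optimal objective.
// [[Rcpp::export]]
List cpp_mst_minsum(NumericMatrix costs, IntegerVector parent,
                    IntegerVector order, NumericMatrix labels, double theta) {
  int n = costs.nrow(), L = costs.ncol();
  std::vector<double> bel(costs.begin(), costs.end()); // n x L col-major
  std::vector<int> amin((size_t)n * L, 0);
  // pairwise distance table
  std::vector<double> D((size_t)L * L);
  for (int f = 0; f < L; f++)
    for (int g = 0; g < L; g++) {
      double s = 0;
      for (int c = 0; c < 3; c++) {
        double d = labels(f, c) - labels(g, c);
        s += d * d;
      }
      D[f + (size_t)L * g] = s;
    }
  // leaves to root
  std::vector<double> row(L);
  for (int t = n - 1; t >= 1; t--) {
    int node = order[t] - 1;
    int par = parent[node] - 1;
    for (int fc = 0; fc < L; fc++) row[fc] = bel[node + (size_t)n * fc];
    for (int fp = 0; fp < L; fp++) {
      double best = R_PosInf; int barg = 0;
      for (int fc = 0; fc < L; fc++) {
        double cnd = row[fc] + theta * D[fc + (size_t)L * fp];
        if (cnd < best) { best = cnd; barg = fc; }
      }
      amin[node + (size_t)n * fp] = barg;
      bel[node + (size_t)n * fp] = best; // now holds the message m_node(fp)
      bel[par + (size_t)n * fp] += best;
    }
  }
  int root = order[0] - 1;
  IntegerVector lab(n);
  double best = R_PosInf; int barg = 0;
  for (int f = 0; f < L; f++)
    if (bel[root + (size_t)n * f] < best) { best = bel[root + (size_t)n * f]; barg = f; }
  if (!R_FINITE(best)) stop("no finite labeling exists");
  lab[root] = barg + 1;
  // root to leaves
  for (int t = 1; t < n; t++) {
    int node = order[t] - 1;
    int par = parent[node] - 1;
    int fp = lab[par] - 1;
    lab[node] = amin[node + (size_t)n * fp] + 1;
  }
  return List::create(_["labels"] = lab, _["objective"] = best);
}
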