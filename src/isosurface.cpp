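#include <Rcpp.h>
#include <map>
#include <cmath>
using namespace Rcpp;

// Isosurface extraction by tetrahedral decomposition of the voxel lattice
// (marching-tetrahedra variant of marching cubes). Each cell between eight
// voxel centres is split into six tetrahedra sharing the main diagonal;
// interpolated crossing vertices are welded per lattice edge, which makes
// the surface watertight. Triangles are oriented so normals point from the
// high-value side (inside, e.g. blood pool) outwards.

static inline long long lin(int i, int j, int k, int nx, int ny) {
  return i + (long long)nx * (j + (long long)ny * k);
}

// six tetrahedra of a unit cube, corners indexed 0..7 (x + 2y + 4z)
static const int TETS[6][4] = {
  {0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
  {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}
};
static const int CORNER[8][3] = {
  {0,0,0},{1,0,0},{0,1,0},{1,1,0},{0,0,1},{1,0,1},{0,1,1},{1,1,1}
};

struct MeshAcc {
  std::map<std::pair<long long,long long>, int> edge2vid;
  std::vector<double> verts;   // x,y,z triples
  std::vector<int> tris;       // 0-based triples
};

static int edge_vertex(MeshAcc& m, long long ga, long long gb,
                       const double* px, double va, double vb, double iso,
                       const double* pa, const double* pb) {
  (void)px;
  if (ga > gb) { std::swap(ga, gb); std::swap(va, vb); std::swap(pa, pb); }
  auto key = std::make_pair(ga, gb);
  auto it = m.edge2vid.find(key);
  if (it != m.edge2vid.end()) return it->second;
  double t = (iso - va) / (vb - va);
  if (t < 1e-6) t = 1e-6;
  if (t > 1 - 1e-6) t = 1 - 1e-6;
  int vid = (int)(m.verts.size() / 3);
  for (int c = 0; c < 3; c++) m.verts.push_back(pa[c] + t * (pb[c] - pa[c]));
  m.edge2vid[key] = vid;
  return vid;
}

// [[Rcpp::export]]
List cpp_isosurface(NumericVector vol, IntegerVector dim, double iso,
                    NumericVector origin, NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  const double* v = vol.begin();
  MeshAcc m;
  double cpos[8][3];
  double cval[8];
  long long cgid[8];
  for (int k = 0; k < nz - 1; k++)
    for (int j = 0; j < ny - 1; j++)
      for (int i = 0; i < nx - 1; i++) {
        bool above = false, below = false;
        for (int c = 0; c < 8; c++) {
          int ii = i + CORNER[c][0], jj = j + CORNER[c][1], kk = k + CORNER[c][2];
          cgid[c] = lin(ii, jj, kk, nx, ny);
          double val = v[cgid[c]];
          if (val == iso) val = iso + 1e-9 * (std::fabs(iso) + 1.0);
          cval[c] = val;
          cpos[c][0] = origin[0] + ii * spacing[0];
          cpos[c][1] = origin[1] + jj * spacing[1];
          cpos[c][2] = origin[2] + kk * spacing[2];
          if (val > iso) above = true; else below = true;
        }
        if (!above || !below) continue;
        for (int t = 0; t < 6; t++) {
          const int* T = TETS[t];
          int in[4], ni = 0, out[4], no = 0;
          for (int c = 0; c < 4; c++) {
            if (cval[T[c]] > iso) in[ni++] = T[c]; else out[no++] = T[c];
          }
          if (ni == 0 || ni == 4) continue;
          int tri[6], ntri = 0;
          if (ni == 1 || ni == 3) {
            int apexc = (ni == 1) ? in[0] : out[0];
            int* others = (ni == 1) ? out : in;
            int e[3];
            for (int c = 0; c < 3; c++)
              e[c] = edge_vertex(m, cgid[apexc], cgid[others[c]], v,
                                 cval[apexc], cval[others[c]], iso,
                                 cpos[apexc], cpos[others[c]]);
            tri[0] = e[0]; tri[1] = e[1]; tri[2] = e[2]; ntri = 1;
          } else { // 2 in, 2 out -> quad -> two triangles
            int e00 = edge_vertex(m, cgid[in[0]], cgid[out[0]], v, cval[in[0]],
                                  cval[out[0]], iso, cpos[in[0]], cpos[out[0]]);
            int e01 = edge_vertex(m, cgid[in[0]], cgid[out[1]], v, cval[in[0]],
                                  cval[out[1]], iso, cpos[in[0]], cpos[out[1]]);
            int e10 = edge_vertex(m, cgid[in[1]], cgid[out[0]], v, cval[in[1]],
                                  cval[out[0]], iso, cpos[in[1]], cpos[out[0]]);
            int e11 = edge_vertex(m, cgid[in[1]], cgid[out[1]], v, cval[in[1]],
                                  cval[out[1]], iso, cpos[in[1]], cpos[out[1]]);
            tri[0] = e00; tri[1] = e01; tri[2] = e11;
            tri[3] = e00; tri[4] = e11; tri[5] = e10;
            ntri = 2;
          }
          // orient: normal should point from inside (val > iso) outward,
          // i.e. along -grad(field). Use the tet's value gradient.
          double gc[3] = {0, 0, 0}, cc[3] = {0, 0, 0};
          for (int c = 0; c < 4; c++)
            for (int d = 0; d < 3; d++) cc[d] += 0.25 * cpos[T[c]][d];
          // least-squares-free gradient: sum over corners of val * (pos - centroid)
          for (int c = 0; c < 4; c++)
            for (int d = 0; d < 3; d++)
              gc[d] += cval[T[c]] * (cpos[T[c]][d] - cc[d]);
          for (int q = 0; q < ntri; q++) {
            int a = tri[3 * q], b = tri[3 * q + 1], cidx = tri[3 * q + 2];
            double* A = &m.verts[3 * a];
            double* B = &m.verts[3 * b];
            double* C = &m.verts[3 * cidx];
            double u1[3], u2[3], nrm[3];
            for (int d = 0; d < 3; d++) { u1[d] = B[d] - A[d]; u2[d] = C[d] - A[d]; }
            nrm[0] = u1[1] * u2[2] - u1[2] * u2[1];
            nrm[1] = u1[2] * u2[0] - u1[0] * u2[2];
            nrm[2] = u1[0] * u2[1] - u1[1] * u2[0];
            double dp = nrm[0] * gc[0] + nrm[1] * gc[1] + nrm[2] * gc[2];
            if (dp > 0) std::swap(b, cidx); // normal opposes the gradient
            m.tris.push_back(a); m.tris.push_back(b); m.tris.push_back(cidx);
          }
        }
      }
  int nv = (int)(m.verts.size() / 3), nt = (int)(m.tris.size() / 3);
  NumericMatrix verts(nv, 3);
  IntegerMatrix tris(nt, 3);
  for (int a = 0; a < nv; a++)
    for (int d = 0; d < 3; d++) verts(a, d) = m.verts[3 * a + d];
  for (int a = 0; a < nt; a++)
    for (int d = 0; d < 3; d++) tris(a, d) = m.tris[3 * a + d] + 1; // 1-based
  return List::create(_["vertices"] = verts, _["triangles"] = tris);
}
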