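#include <Rcpp.h>
#include <cmath>
#include <map>
#include <utility>
#include <vector>
using namespace Rcpp;

// Isosurface extraction by tetrahedral marching on the uniform Kuhn (6-tet)
// decomposition of the voxel-centre lattice. Every cube is split the same
// way, so shared cube faces carry the same diagonal and the surface is
// watertight on closed fields. Vertices are welded per lattice edge, and
// triangles are oriented with outward normals (away from values > level).
//
// field is sampled at voxel centres; the caller pads with background so the
// surface closes at the volume border. Vertex coordinates are returned in
// fractional 0-based voxel indices; the caller maps them to mm.

namespace {

struct EdgeKey {
  long long a, b;
  bool operator<(const EdgeKey& o) const {
    return a < o.a || (a == o.a && b < o.b);
  }
};

}  // namespace

// [[Rcpp::export]]
List march_tets_cpp(NumericVector field, IntegerVector dims, double level) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long long NX = nx, NXY = (long long)nx * ny;

  // Kuhn tetrahedra of the unit cube, corner index = i + 2j + 4k
  static const int TETS[6][4] = {
    {0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
    {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}};
  static const int CX[8] = {0, 1, 0, 1, 0, 1, 0, 1};
  static const int CY[8] = {0, 0, 1, 1, 0, 0, 1, 1};
  static const int CZ[8] = {0, 0, 0, 0, 1, 1, 1, 1};

  std::map<EdgeKey, int> vmap;
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;

  double cpx[8], cpy[8], cpz[8], cv[8];
  long long gid[8];

  for (int k = 0; k + 1 < nz; ++k) {
    for (int j = 0; j + 1 < ny; ++j) {
      for (int i = 0; i + 1 < nx; ++i) {
        bool anyIn = false, anyOut = false;
        for (int c = 0; c < 8; ++c) {
          const int x = i + CX[c], y = j + CY[c], z = k + CZ[c];
          const long long g = x + NX * y + NXY * z;
          gid[c] = g;
          cpx[c] = x; cpy[c] = y; cpz[c] = z;
          cv[c] = field[g];
          if (cv[c] > level) anyIn = true; else anyOut = true;
        }
        if (!anyIn || !anyOut) continue;

        for (int t = 0; t < 6; ++t) {
          const int* T = TETS[t];
          int ins[4], outs[4];
          int ni = 0, no = 0;
          for (int c = 0; c < 4; ++c) {
            if (cv[T[c]] > level) ins[ni++] = T[c];
            else outs[no++] = T[c];
          }
          if (ni == 0 || ni == 4) continue;

          // interpolated vertex on lattice edge (a inside, b outside)
          std::vector<int> ev;  // welded vertex ids, one per (in,out) pair
          for (int a = 0; a < ni; ++a) {
            for (int b = 0; b < no; ++b) {
              const int ia = ins[a], ib = outs[b];
              EdgeKey key;
              key.a = std::min(gid[ia], gid[ib]);
              key.b = std::max(gid[ia], gid[ib]);
              std::map<EdgeKey, int>::iterator it = vmap.find(key);
              int id;
              if (it == vmap.end()) {
                const double va = cv[ia], vb = cv[ib];
                const double u = (level - va) / (vb - va);
                vx.push_back(cpx[ia] + u * (cpx[ib] - cpx[ia]));
                vy.push_back(cpy[ia] + u * (cpy[ib] - cpy[ia]));
                vz.push_back(cpz[ia] + u * (cpz[ib] - cpz[ia]));
                id = (int)vx.size() - 1;
                vmap[key] = id;
              } else {
                id = it->second;
              }
              ev.push_back(id);
            }
          }

          // centroid of inside corners (for orientation)
          double inx = 0, iny = 0, inz = 0;
          for (int a = 0; a < ni; ++a) {
            inx += cpx[ins[a]]; iny += cpy[ins[a]]; inz += cpz[ins[a]];
          }
          inx /= ni; iny /= ni; inz /= ni;

          int t1[2][3];
          int ntri = 0;
          if (ni == 1 || ni == 3) {
            t1[0][0] = ev[0]; t1[0][1] = ev[1]; t1[0][2] = ev[2];
            ntri = 1;
          } else {  // ni == 2: ev order is (i0o0, i0o1, i1o0, i1o1) -> quad
            t1[0][0] = ev[0]; t1[0][1] = ev[1]; t1[0][2] = ev[3];
            t1[1][0] = ev[0]; t1[1][1] = ev[3]; t1[1][2] = ev[2];
            ntri = 2;
          }
          for (int q = 0; q < ntri; ++q) {
            const int A = t1[q][0], B = t1[q][1], C = t1[q][2];
            if (A == B || B == C || A == C) continue;
            const double ux = vx[B] - vx[A], uy = vy[B] - vy[A],
                         uz = vz[B] - vz[A];
            const double wx = vx[C] - vx[A], wy = vy[C] - vy[A],
                         wz = vz[C] - vz[A];
            const double nxn = uy * wz - uz * wy;
            const double nyn = uz * wx - ux * wz;
            const double nzn = ux * wy - uy * wx;
            const double dx = inx - vx[A], dy = iny - vy[A], dz = inz - vz[A];
            const double d = nxn * dx + nyn * dy + nzn * dz;
            if (d > 0) {  // normal points toward inside: flip
              tri.push_back(A); tri.push_back(C); tri.push_back(B);
            } else {
              tri.push_back(A); tri.push_back(B); tri.push_back(C);
            }
          }
        }
      }
    }
  }

  const int nv = (int)vx.size();
  NumericMatrix Vout(nv, 3);
  for (int v = 0; v < nv; ++v) {
    Vout(v, 0) = vx[v]; Vout(v, 1) = vy[v]; Vout(v, 2) = vz[v];
  }
  const int nf = (int)tri.size() / 3;
  IntegerMatrix Fout(nf, 3);
  for (int f = 0; f < nf; ++f) {
    Fout(f, 0) = tri[3 * f] + 1;      // 1-based for R
    Fout(f, 1) = tri[3 * f + 1] + 1;
    Fout(f, 2) = tri[3 * f + 2] + 1;
  }
  return List::create(_["vertices"] = Vout, _["faces"] = Fout);
}
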