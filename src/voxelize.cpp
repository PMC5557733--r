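#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Scanline voxelization of a closed triangle mesh. Voxel (i,j,k) centre is
// origin + (i+0.5, j+0.5, k+0.5) * spacing (0-based). For every (x,y) voxel
// column a +z ray is intersected with the mesh and voxels between odd/even
// crossing pairs are marked inside. Ray origins are nudged off lattice
// positions by a fixed sub-voxel offset so rays never hit edges/vertices of
// a generic mesh exactly.
// [[Rcpp::export]]
LogicalVector voxelize_cpp(NumericMatrix V, IntegerMatrix F,
                           IntegerVector dims, NumericVector origin,
                           double spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const int nf = F.nrow();
  LogicalVector out(n, false);

  // deterministic irrational nudge, tiny fraction of a voxel
  const double ex = 0.5 + 1.2345e-4 * 0.6180339887;
  const double ey = 0.5 + 1.2345e-4 * 0.3819660113;

  // bin triangles into the (x, y) column grid by their 2D bounding box
  std::vector<std::vector<int> > bins((size_t)nx * ny);
  for (int f = 0; f < nf; ++f) {
    double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
    for (int c = 0; c < 3; ++c) {
      const int v = F(f, c) - 1;  // faces arrive 1-based from R
      xmin = std::min(xmin, V(v, 0)); xmax = std::max(xmax, V(v, 0));
      ymin = std::min(ymin, V(v, 1)); ymax = std::max(ymax, V(v, 1));
    }
    int i0 = (int)std::floor((xmin - origin[0]) / spacing - ex) ;
    int i1 = (int)std::ceil((xmax - origin[0]) / spacing - ex);
    int j0 = (int)std::floor((ymin - origin[1]) / spacing - ey);
    int j1 = (int)std::ceil((ymax - origin[1]) / spacing - ey);
    i0 = std::max(i0, 0); j0 = std::max(j0, 0);
    i1 = std::min(i1, nx - 1); j1 = std::min(j1, ny - 1);
    for (int j = j0; j <= j1; ++j)
      for (int i = i0; i <= i1; ++i)
        bins[(size_t)i + (size_t)nx * j].push_back(f);
  }

  std::vector<double> zs;
  for (int j = 0; j < ny; ++j) {
    const double cy = origin[1] + (j + ey) * spacing;
    for (int i = 0; i < nx; ++i) {
      const double cx = origin[0] + (i + ex) * spacing;
      const std::vector<int>& tris = bins[(size_t)i + (size_t)nx * j];
      if (tris.empty()) continue;
      zs.clear();
      for (size_t t = 0; t < tris.size(); ++t) {
        const int f = tris[t];
        const int a = F(f, 0) - 1, b = F(f, 1) - 1, c = F(f, 2) - 1;
        // 2D barycentric test in the xy plane
        const double x0 = V(a, 0) - cx, y0 = V(a, 1) - cy;
        const double x1 = V(b, 0) - cx, y1 = V(b, 1) - cy;
        const double x2 = V(c, 0) - cx, y2 = V(c, 1) - cy;
        const double d01 = x0 * y1 - x1 * y0;
        const double d12 = x1 * y2 - x2 * y1;
        const double d20 = x2 * y0 - x0 * y2;
        const double area = d01 + d12 + d20;
        if (area == 0.0) continue; // degenerate in projection
        const bool pos = area > 0.0;
        if ((d01 > 0) == pos && (d12 > 0) == pos && (d20 > 0) == pos) {
          const double w0 = d12 / area, w1 = d20 / area, w2 = d01 / area;
          zs.push_back(w0 * V(a, 2) + w1 * V(b, 2) + w2 * V(c, 2));
        }
      }
      if (zs.size() < 2) continue;
      std::sort(zs.begin(), zs.end());
      for (size_t t = 0; t + 1 < zs.size(); t += 2) {
        int k0 = (int)std::ceil((zs[t] - origin[2]) / spacing - 0.5);
        int k1 = (int)std::floor((zs[t + 1] - origin[2]) / spacing - 0.5);
        k0 = std::max(k0, 0);
        k1 = std::min(k1, nz - 1);
        for (int k = k0; k <= k1; ++k)
          out[(R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = true;
      }
    }
  }
  return out;
}
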