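#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Binary erosion/dilation with a discrete ball structuring element
// (offsets with dx^2+dy^2+dz^2 <= r^2). Out-of-bounds voxels count as
// background, so erosion eats the volume border.
// [[Rcpp::export]]
LogicalVector morph_ball_cpp(LogicalVector mask, IntegerVector dims,
                             double r, bool dilate) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const int ri = (int)std::floor(r);
  std::vector<int> dxs, dys, dzs;
  for (int dz = -ri; dz <= ri; ++dz)
    for (int dy = -ri; dy <= ri; ++dy)
      for (int dx = -ri; dx <= ri; ++dx)
        if ((double)(dx * dx + dy * dy + dz * dz) <= r * r + 1e-12) {
          dxs.push_back(dx); dys.push_back(dy); dzs.push_back(dz);
        }
  const int nn = (int)dxs.size();
  LogicalVector out(n);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const R_xlen_t p = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        bool v = dilate ? false : true;
        for (int k = 0; k < nn; ++k) {
          const int xx = x + dxs[k], yy = y + dys[k], zz = z + dzs[k];
          bool m;
          if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
            m = false;
          else
            m = mask[xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)];
          if (dilate) { if (m) { v = true; break; } }
          else        { if (!m) { v = false; break; } }
        }
        out[p] = v;
      }
  return out;
}

// 26-connected component labelling (BFS), labels 1..k by discovery order.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> queue;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    queue.clear();
    queue.push_back(s);
    while (!queue.empty()) {
      const R_xlen_t p = queue.back();
      queue.pop_back();
      const int x = (int)(p % nx);
      const int y = (int)((p / nx) % ny);
      const int z = (int)(p / ((R_xlen_t)nx * ny));
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            const int xx = x + dx, yy = y + dy, zz = z + dz;
            if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
              continue;
            const R_xlen_t q = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
            if (mask[q] && lab[q] == 0) { lab[q] = next; queue.push_back(q); }
          }
    }
  }
  return lab;
}
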