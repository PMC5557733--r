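#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Synchronous GrowCut cellular automaton on a 3D grid.
// intensity: range-normalised to [0,1] by the caller, so the attack
// attenuation is g(x) = 1 - |C_p - C_q|.
// label: 0 = unlabeled, 1 = foreground, 2 = background.
// [[Rcpp::export]]
List growcut_cpp(NumericVector intensity, IntegerVector dims,
                 IntegerVector label0, NumericVector strength0,
                 int max_iters, int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;

  std::vector<int> dxs, dys, dzs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        dxs.push_back(dx); dys.push_back(dy); dzs.push_back(dz);
      }
  const int nn = (int)dxs.size();

  std::vector<int> lab(label0.begin(), label0.end());
  std::vector<double> str(strength0.begin(), strength0.end());
  std::vector<int> labN(n);
  std::vector<double> strN(n);

  bool converged = false;
  int iter = 0;
  while (iter < max_iters) {
    bool changed = false;
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < ny; ++y) {
        for (int x = 0; x < nx; ++x) {
          const R_xlen_t p = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
          int bl = lab[p];
          double bs = str[p];
          const double cp = intensity[p];
          for (int k = 0; k < nn; ++k) {
            const int xx = x + dxs[k], yy = y + dys[k], zz = z + dzs[k];
            if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
              continue;
            const R_xlen_t q = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
            if (lab[q] == 0) continue;
            const double g = (1.0 - std::fabs(cp - intensity[q])) * str[q];
            if (g > bs) { bs = g; bl = lab[q]; }
          }
          labN[p] = bl;
          strN[p] = bs;
          if (bl != lab[p]) changed = true;
        }
      }
    }
    std::swap(lab, labN);
    std::swap(str, strN);
    ++iter;
    if (!changed) { converged = true; break; }
  }

  IntegerVector outLab(n);
  NumericVector outStr(n);
  for (R_xlen_t i = 0; i < n; ++i) { outLab[i] = lab[i]; outStr[i] = str[i]; }
  return List::create(_["label"] = outLab, _["strength"] = outStr,
                      _["iterations"] = iter, _["converged"] = converged);
}
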