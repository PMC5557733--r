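#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Exact closest point on a triangle mesh, accelerated by a uniform grid over
// triangle bounding boxes with expanding-shell search. Ties in distance keep
// the lowest triangle index (candidates are scanned in index order within a
// shell and replacement requires a strictly smaller distance).

namespace {

// Ericson-style closest point on triangle abc to point p
inline void closestPtTri(const double* p, const double* a, const double* b,
                         const double* c, double* out) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i]; ac[i] = c[i] - a[i]; ap[i] = p[i] - a[i];
  }
  const double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  const double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) { for (int i = 0; i < 3; ++i) out[i] = a[i]; return; }
  double bp[3];
  for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
  const double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  const double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0.0 && d4 <= d3) { for (int i = 0; i < 3; ++i) out[i] = b[i]; return; }
  const double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    const double v = d1 / (d1 - d3);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + v * ab[i];
    return;
  }
  double cp[3];
  for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
  const double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
  const double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
  if (d6 >= 0.0 && d5 <= d6) { for (int i = 0; i < 3; ++i) out[i] = c[i]; return; }
  const double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    const double w = d2 / (d2 - d6);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + w * ac[i];
    return;
  }
  const double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    const double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i = 0; i < 3; ++i) out[i] = b[i] + w * (c[i] - b[i]);
    return;
  }
  const double denom = 1.0 / (va + vb + vc);
  const double v = vb * denom, w = vc * denom;
  for (int i = 0; i < 3; ++i) out[i] = a[i] + ab[i] * v + ac[i] * w;
}

}  // namespace

// [[Rcpp::export]]
List closest_point_mesh_cpp(NumericMatrix P, NumericMatrix V, IntegerMatrix F) {
  const int np = P.nrow(), nf = F.nrow();

  // mesh bounding box
  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) { lo[d] = R_PosInf; hi[d] = R_NegInf; }
  for (int v = 0; v < V.nrow(); ++v)
    for (int d = 0; d < 3; ++d) {
      lo[d] = std::min(lo[d], V(v, d));
      hi[d] = std::max(hi[d], V(v, d));
    }
  double diag = 0;
  for (int d = 0; d < 3; ++d) diag = std::max(diag, hi[d] - lo[d]);
  if (diag <= 0) diag = 1.0;

  // cell size: mean triangle bbox extent, floored at diag/128
  double meanext = 0;
  for (int f = 0; f < nf; ++f) {
    double ext = 0;
    for (int d = 0; d < 3; ++d) {
      double mn = R_PosInf, mx = R_NegInf;
      for (int c = 0; c < 3; ++c) {
        mn = std::min(mn, V(F(f, c) - 1, d));
        mx = std::max(mx, V(F(f, c) - 1, d));
      }
      ext = std::max(ext, mx - mn);
    }
    meanext += ext;
  }
  meanext = nf > 0 ? meanext / nf : diag;
  double cell = std::max(meanext * 1.5, diag / 128.0);

  int gdim[3];
  for (int d = 0; d < 3; ++d)
    gdim[d] = std::max(1, (int)std::ceil((hi[d] - lo[d]) / cell) + 1);
  const size_t ncell = (size_t)gdim[0] * gdim[1] * gdim[2];
  std::vector<std::vector<int> > bins(ncell);
  for (int f = 0; f < nf; ++f) {
    int c0[3], c1[3];
    for (int d = 0; d < 3; ++d) {
      double mn = R_PosInf, mx = R_NegInf;
      for (int c = 0; c < 3; ++c) {
        mn = std::min(mn, V(F(f, c) - 1, d));
        mx = std::max(mx, V(F(f, c) - 1, d));
      }
      c0[d] = std::max(0, std::min(gdim[d] - 1, (int)std::floor((mn - lo[d]) / cell)));
      c1[d] = std::max(0, std::min(gdim[d] - 1, (int)std::floor((mx - lo[d]) / cell)));
    }
    for (int z = c0[2]; z <= c1[2]; ++z)
      for (int y = c0[1]; y <= c1[1]; ++y)
        for (int x = c0[0]; x <= c1[0]; ++x)
          bins[(size_t)x + (size_t)gdim[0] * (y + (size_t)gdim[1] * z)].push_back(f);
  }

  NumericMatrix CP(np, 3);
  NumericVector D(np);
  IntegerVector TI(np);
  const int maxshell = gdim[0] + gdim[1] + gdim[2] + 2;
  std::vector<int> cand;

  for (int q = 0; q < np; ++q) {
    double p[3];
    for (int d = 0; d < 3; ++d) p[d] = P(q, d);
    int pc[3];
    for (int d = 0; d < 3; ++d) {
      pc[d] = (int)std::floor((p[d] - lo[d]) / cell);
      pc[d] = std::max(0, std::min(gdim[d] - 1, pc[d]));
    }

    double best = R_PosInf, bestpt[3] = {0, 0, 0};
    int besttri = -1;

    for (int k = 0; k <= maxshell; ++k) {
      if (besttri >= 0 && (double)(k - 1) * cell > std::sqrt(best)) break;
      cand.clear();
      // cells with Chebyshev distance k from pc, clipped to the grid
      const int x0 = std::max(0, pc[0] - k), x1 = std::min(gdim[0] - 1, pc[0] + k);
      const int y0 = std::max(0, pc[1] - k), y1 = std::min(gdim[1] - 1, pc[1] + k);
      const int z0 = std::max(0, pc[2] - k), z1 = std::min(gdim[2] - 1, pc[2] + k);
      for (int z = z0; z <= z1; ++z)
        for (int y = y0; y <= y1; ++y)
          for (int x = x0; x <= x1; ++x) {
            const int ch = std::max(std::abs(x - pc[0]),
                          std::max(std::abs(y - pc[1]), std::abs(z - pc[2])));
            if (ch != k) continue;
            const std::vector<int>& b =
                bins[(size_t)x + (size_t)gdim[0] * (y + (size_t)gdim[1] * z)];
            cand.insert(cand.end(), b.begin(), b.end());
          }
      if (cand.empty()) continue;
      std::sort(cand.begin(), cand.end());
      cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
      for (size_t t = 0; t < cand.size(); ++t) {
        const int f = cand[t];
        double a[3], b[3], c[3], cp[3];
        for (int d = 0; d < 3; ++d) {
          a[d] = V(F(f, 0) - 1, d);
          b[d] = V(F(f, 1) - 1, d);
          c[d] = V(F(f, 2) - 1, d);
        }
        closestPtTri(p, a, b, c, cp);
        double d2 = 0;
        for (int d = 0; d < 3; ++d) d2 += (cp[d] - p[d]) * (cp[d] - p[d]);
        if (d2 < best) {
          best = d2;
          besttri = f;
          for (int d = 0; d < 3; ++d) bestpt[d] = cp[d];
        }
      }
    }
    for (int d = 0; d < 3; ++d) CP(q, d) = bestpt[d];
    D[q] = std::sqrt(best);
    TI[q] = besttri + 1;
  }
  return List::create(_["points"] = CP, _["distance"] = D, _["triangle"] = TI);
}
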