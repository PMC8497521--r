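#include <Rcpp.h>
#include <array>
#include <cstdlib>
#include <vector>
using namespace Rcpp;

// Connected-component labeling of a 3D logical mask. Connectivity 6, 18 or
// 26 (face / face+edge / face+edge+corner neighbors). Components are
// numbered 1..K in raster-scan order of their first-encountered voxel,
// which makes the labeling deterministic.
// [[Rcpp::export]]
List label_components_3d(LogicalVector mask, IntegerVector dims,
                         int connectivity) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t n = mask.size();
  IntegerVector lab(n);
  lab.attr("dim") = dims;

  std::vector<std::array<int, 3> > offs;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        if (di == 0 && dj == 0 && dk == 0) continue;
        const int man = std::abs(di) + std::abs(dj) + std::abs(dk);
        if (connectivity == 6 && man > 1) continue;
        if (connectivity == 18 && man > 2) continue;
        offs.push_back({{di, dj, dk}});
      }

  int K = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t idx = 0; idx < n; ++idx) {
    if (!mask[idx] || lab[idx] != 0) continue;
    ++K;
    lab[idx] = K;
    stack.push_back(idx);
    while (!stack.empty()) {
      const R_xlen_t cur = stack.back();
      stack.pop_back();
      const int i = (int)(cur % n1);
      const R_xlen_t r = cur / n1;
      const int j = (int)(r % n2);
      const int k = (int)(r / n2);
      for (std::size_t o = 0; o < offs.size(); ++o) {
        const int ii = i + offs[o][0];
        const int jj = j + offs[o][1];
        const int kk = k + offs[o][2];
        if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 || kk < 0 || kk >= n3)
          continue;
        const R_xlen_t nb = ii + (R_xlen_t)n1 * (jj + (R_xlen_t)n2 * kk);
        if (mask[nb] && lab[nb] == 0) {
          lab[nb] = K;
          stack.push_back(nb);
        }
      }
    }
  }
  return List::create(_["labels"] = lab, _["k"] = K);
}
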