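#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// 3x3x3 median filter with edge replication (indices clamped at the
// borders), so the output never dims object borders at the stack boundary.
// Per-axis neighbor indices are precomputed and the 27-value neighborhood
// is gathered with raw pointers; the median is the 14th order statistic.
// [[Rcpp::export]]
NumericVector median_filter_3d(NumericVector x, IntegerVector dims) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  NumericVector out(x.size());
  out.attr("dim") = dims;
  const double *px = x.begin();
  double *po = out.begin();

  // clamped neighbor index tables per axis
  std::vector<int> i0(n1), i2(n1), j0(n2), j2(n2), k0(n3), k2(n3);
  for (int i = 0; i < n1; ++i) {
    i0[i] = i > 0 ? i - 1 : 0;
    i2[i] = i < n1 - 1 ? i + 1 : n1 - 1;
  }
  for (int j = 0; j < n2; ++j) {
    j0[j] = j > 0 ? j - 1 : 0;
    j2[j] = j < n2 - 1 ? j + 1 : n2 - 1;
  }
  for (int k = 0; k < n3; ++k) {
    k0[k] = k > 0 ? k - 1 : 0;
    k2[k] = k < n3 - 1 ? k + 1 : n3 - 1;
  }

  double buf[27];
  for (int k = 0; k < n3; ++k) {
    const R_xlen_t kb[3] = {(R_xlen_t)n1 * n2 * k0[k],
                            (R_xlen_t)n1 * n2 * k,
                            (R_xlen_t)n1 * n2 * k2[k]};
    for (int j = 0; j < n2; ++j) {
      const R_xlen_t jb[3] = {(R_xlen_t)n1 * j0[j], (R_xlen_t)n1 * j,
                              (R_xlen_t)n1 * j2[j]};
      R_xlen_t base[9];
      for (int a = 0; a < 3; ++a)
        for (int b = 0; b < 3; ++b) base[3 * a + b] = kb[a] + jb[b];
      const R_xlen_t orow = (R_xlen_t)n1 * j + (R_xlen_t)n1 * n2 * k;
      for (int i = 0; i < n1; ++i) {
        const int ii[3] = {i0[i], i, i2[i]};
        int m = 0;
        for (int a = 0; a < 9; ++a) {
          const double *p = px + base[a];
          buf[m++] = p[ii[0]];
          buf[m++] = p[ii[1]];
          buf[m++] = p[ii[2]];
        }
        std::nth_element(buf, buf + 13, buf + 27);
        po[orow + i] = buf[13];
      }
    }
  }
  return out;
}
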