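// Hot-path raster kernels for sliding-window screening: binary morphology
// and connected-component labelling on small crops. Kept minimal on
// purpose; everything else lives in R.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Connected-component labelling (iterative flood fill).
// connectivity: 8 for foreground objects, 4 for background holes (the
// standard dual pair).
// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(const IntegerMatrix& bin, int connectivity = 8) {
  const int nr = bin.nrow(), nc = bin.ncol();
  IntegerMatrix lab(nr, nc);
  static const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  static const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  static const int dr4[4] = {-1, 1, 0, 0};
  static const int dc4[4] = {0, 0, -1, 1};
  const int nn = (connectivity == 8) ? 8 : 4;
  const int* dr = (connectivity == 8) ? dr8 : dr4;
  const int* dc = (connectivity == 8) ? dc8 : dc4;
  std::vector<int> stack;
  int next = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (bin(i, j) != 0 && lab(i, j) == 0) {
        ++next;
        lab(i, j) = next;
        stack.push_back(i + j * nr);
        while (!stack.empty()) {
          const int p = stack.back();
          stack.pop_back();
          const int pi = p % nr, pj = p / nr;
          for (int k = 0; k < nn; ++k) {
            const int qi = pi + dr[k], qj = pj + dc[k];
            if (qi >= 0 && qi < nr && qj >= 0 && qj < nc &&
                bin(qi, qj) != 0 && lab(qi, qj) == 0) {
              lab(qi, qj) = next;
              stack.push_back(qi + qj * nr);
            }
          }
        }
      }
    }
  }
  return lab;
}

// Binary closing (dilation then erosion) with a disc structuring element
// of the given diameter; pixels outside the image count as background.
// [[Rcpp::export(name = ".binary_close")]]
IntegerMatrix binary_close(const IntegerMatrix& bin, int size = 5) {
  const int nr = bin.nrow(), nc = bin.ncol();
  const double r = size / 2.0, r2 = r * r;
  const int ri = (int)std::floor(r);
  std::vector<int> offr, offc;
  for (int a = -ri; a <= ri; ++a)
    for (int b = -ri; b <= ri; ++b)
      if (a * a + b * b <= r2) {
        offr.push_back(a);
        offc.push_back(b);
      }
  const int K = (int)offr.size();
  IntegerMatrix dil(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (bin(i, j) != 0)
        for (int k = 0; k < K; ++k) {
          const int qi = i + offr[k], qj = j + offc[k];
          if (qi >= 0 && qi < nr && qj >= 0 && qj < nc) dil(qi, qj) = 1;
        }
  IntegerMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      bool all = true;
      for (int k = 0; k < K && all; ++k) {
        const int qi = i + offr[k], qj = j + offc[k];
        if (qi < 0 || qi >= nr || qj < 0 || qj >= nc || dil(qi, qj) == 0)
          all = false;
      }
      out(i, j) = all ? 1 : 0;
    }
  return out;
}
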