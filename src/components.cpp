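#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labelling on a logical raster.
// connectivity: 8 (foreground convention) or 4 (used on the background
// complement when filling holes, so that 8-connected foreground has
// 4-connected background).
// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(LogicalMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next_label = 0;
  std::vector<int> stack;
  stack.reserve(256);
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 0, 0, 1};
  const int dc4[4] = {0, -1, 1, 0};
  int nnb = (connectivity == 8) ? 8 : 4;
  const int *dr = (connectivity == 8) ? dr8 : dr4;
  const int *dc = (connectivity == 8) ? dc8 : dc4;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next_label;
      stack.push_back(i + j * nr);
      lab(i, j) = next_label;
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int ci = idx % nr, cj = idx / nr;
        for (int k = 0; k < nnb; ++k) {
          int ni = ci + dr[k], nj = cj + dc[k];
          if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
          if (mask(ni, nj) && lab(ni, nj) == 0) {
            lab(ni, nj) = next_label;
            stack.push_back(ni + nj * nr);
          }
        }
      }
    }
  }
  return lab;
}

// Grayscale erosion (op = 0) / dilation (op = 1) with a disc structuring
// element of the given pixel radius. Out-of-bounds neighbours are ignored,
// which preserves constants under opening/closing.
// [[Rcpp::export(name = ".gray_morph")]]
NumericMatrix gray_morph(NumericMatrix img, int radius, int op) {
  int nr = img.nrow(), nc = img.ncol();
  std::vector<int> offr, offc;
  for (int a = -radius; a <= radius; ++a)
    for (int b = -radius; b <= radius; ++b)
      if (a * a + b * b <= radius * radius) {
        offr.push_back(a);
        offc.push_back(b);
      }
  int nse = (int) offr.size();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double v = img(i, j);
      for (int k = 0; k < nse; ++k) {
        int ni = i + offr[k], nj = j + offc[k];
        if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
        double x = img(ni, nj);
        if (op == 0 ? (x < v) : (x > v)) v = x;
      }
      out(i, j) = v;
    }
  }
  return out;
}
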