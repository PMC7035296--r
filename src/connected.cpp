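#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labelling of a logical mask by breadth-first search.
// connectivity must be 4 or 8. Returns an integer matrix of labels,
// 0 for background, components numbered from 1 in scan order.
// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(LogicalMatrix mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nnb = (connectivity == 4) ? 4 : 8;
  int cur = 0;
  std::vector<int> stack;
  stack.reserve(1024);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++cur;
      lab(i, j) = cur;
      stack.push_back(i + j * nr);
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int ci = idx % nr, cj = idx / nr;
        for (int k = 0; k < nnb; ++k) {
          int ni = ci + dr8[k], nj = cj + dc8[k];
          if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
          if (mask(ni, nj) && lab(ni, nj) == 0) {
            lab(ni, nj) = cur;
            stack.push_back(ni + nj * nr);
          }
        }
      }
    }
  }
  return lab;
}
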