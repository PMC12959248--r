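#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 8-connected component labelling of a binary mask.
// Labels are assigned in row-major first-encounter order so that the
// "first component in scan order" tie-break documented by
// largest_component() is deterministic.
// [[Rcpp::export]]
IntegerMatrix label_components_8(const LogicalMatrix& px) {
  const int nr = px.nrow(), nc = px.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  int next = 0;
  for (int i = 0; i < nr; i++) {
    for (int j = 0; j < nc; j++) {
      if (px(i, j) && lab(i, j) == 0) {
        ++next;
        lab(i, j) = next;
        stack.push_back(i + j * nr);
        while (!stack.empty()) {
          const int p = stack.back();
          stack.pop_back();
          const int r = p % nr, c = p / nr;
          for (int dr = -1; dr <= 1; dr++) {
            for (int dc = -1; dc <= 1; dc++) {
              if (dr == 0 && dc == 0) continue;
              const int rr = r + dr, cc = c + dc;
              if (rr >= 0 && rr < nr && cc >= 0 && cc < nc &&
                  px(rr, cc) && lab(rr, cc) == 0) {
                lab(rr, cc) = next;
                stack.push_back(rr + cc * nr);
              }
            }
          }
        }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}
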