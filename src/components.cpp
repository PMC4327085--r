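#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Label connected components of a binary matrix.
// Labels are assigned in row-major scan order (row 0 first), so the
// component whose top-left-most pixel comes first in row-major order
// gets the smallest label -- the documented size tie-break relies on this.
// connectivity: 4 or 8.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerMatrix label_components_cpp(const IntegerMatrix& mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix labels(nr, nc);
  std::vector<int> stack;
  stack.reserve(1024);
  int next = 0;

  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 0, 0, 1};
  const int dc4[4] = {0, -1, 1, 0};
  const int nnb = (connectivity == 4) ? 4 : 8;
  const int* dr = (connectivity == 4) ? dr4 : dr8;
  const int* dc = (connectivity == 4) ? dc4 : dc8;

  // scan rows first within each column-major matrix: iterate r outer to keep
  // row-major label ordering
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (mask(r, c) != 0 && labels(r, c) == 0) {
        ++next;
        labels(r, c) = next;
        stack.clear();
        stack.push_back(r + c * nr);
        while (!stack.empty()) {
          int idx = stack.back();
          stack.pop_back();
          int cr = idx % nr, cc = idx / nr;
          for (int k = 0; k < nnb; ++k) {
            int r2 = cr + dr[k], c2 = cc + dc[k];
            if (r2 >= 0 && r2 < nr && c2 >= 0 && c2 < nc &&
                mask(r2, c2) != 0 && labels(r2, c2) == 0) {
              labels(r2, c2) = next;
              stack.push_back(r2 + c2 * nr);
            }
          }
        }
      }
    }
  }
  return labels;
}
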