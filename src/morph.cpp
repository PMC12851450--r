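#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// Label connected components of a 2D binary image by flood fill.
// connectivity: 4 (edge-adjacent) or 8 (edge- or corner-adjacent).
// Labels are assigned 1,2,... in column-major scan order of the first pixel
// encountered, so labeling is deterministic.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix img, int connectivity) {
  if (connectivity != 4 && connectivity != 8) stop("connectivity must be 4 or 8");
  const int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix lab(nr, nc);
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nnb = connectivity == 4 ? 4 : 8;
  std::vector<int> stack;
  int next = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (!img(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.clear();
      stack.push_back(r + nr * c);
      while (!stack.empty()) {
        const int p = stack.back();
        stack.pop_back();
        const int pr = p % nr, pc = p / nr;
        for (int k = 0; k < nnb; ++k) {
          const int rr = pr + dr8[k], cc = pc + dc8[k];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (!img(rr, cc) || lab(rr, cc) != 0) continue;
          lab(rr, cc) = next;
          stack.push_back(rr + nr * cc);
        }
      }
    }
  return lab;
}
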