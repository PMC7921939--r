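#include <Rcpp.h>
using namespace Rcpp;

// 3D connected-component labelling on a logical array stored column-major
// with dims (n1, n2, n3).  connectivity: 6 (face) or 26 (face+edge+vertex).
// Returns an integer array of the same shape; 0 = background, components
// numbered 1..k in scan order of their first voxel (deterministic).
// [[Rcpp::export]]
IntegerVector label_components_3d(LogicalVector mask, IntegerVector dims,
                                  int connectivity = 26) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  if (mask.size() != n) stop("mask length does not match dims");
  IntegerVector lab(n, 0);

  // neighbour offsets in (i1,i2,i3)
  std::vector<int> d1, d2, d3;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        int manh = std::abs(a) + std::abs(b) + std::abs(c);
        if (connectivity == 6 && manh != 1) continue;
        d1.push_back(a); d2.push_back(b); d3.push_back(c);
      }
  const int nn = (int)d1.size();

  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      int i3 = (int)(v / ((R_xlen_t)n1 * n2));
      int rem = (int)(v - (R_xlen_t)i3 * n1 * n2);
      int i2 = rem / n1;
      int i1 = rem - i2 * n1;
      for (int k = 0; k < nn; ++k) {
        int j1 = i1 + d1[k], j2 = i2 + d2[k], j3 = i3 + d3[k];
        if (j1 < 0 || j1 >= n1 || j2 < 0 || j2 >= n2 || j3 < 0 || j3 >= n3)
          continue;
        R_xlen_t w = (R_xlen_t)j1 + (R_xlen_t)n1 * (j2 + (R_xlen_t)n2 * j3);
        if (mask[w] && lab[w] == 0) {
          lab[w] = next;
          stack.push_back(w);
        }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}
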