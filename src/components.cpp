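// Connected-component labeling of binary rasters (blob labeling) with
// selectable 4- or 8-connectivity, via iterative BFS flood fill.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".cpp_label_components")]]
List cpp_label_components(IntegerMatrix bin, int connectivity) {
  const int H = bin.nrow(), W = bin.ncol();
  IntegerMatrix labels(H, W);
  std::vector<double> cr, cc;   // centroid accumulators
  std::vector<int> sz;
  std::vector<int> stack;
  int next = 0;
  const int n_off = connectivity == 8 ? 8 : 4;
  const int off_r[8] = { -1, 1, 0, 0, -1, -1, 1, 1 };
  const int off_c[8] = { 0, 0, -1, 1, -1, 1, -1, 1 };
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (bin(i, j) == 0 || labels(i, j) != 0) continue;
      ++next;
      double sr = 0, sc = 0;
      int n = 0;
      stack.clear();
      stack.push_back(i + H * j);
      labels(i, j) = next;
      while (!stack.empty()) {
        const int p = stack.back();
        stack.pop_back();
        const int pr = p % H, pc = p / H;
        sr += pr; sc += pc; ++n;
        for (int k = 0; k < n_off; ++k) {
          const int qr = pr + off_r[k], qc = pc + off_c[k];
          if (qr < 0 || qr >= H || qc < 0 || qc >= W) continue;
          if (bin(qr, qc) == 0 || labels(qr, qc) != 0) continue;
          labels(qr, qc) = next;
          stack.push_back(qr + H * qc);
        }
      }
      cr.push_back(sr / n + 1.0);  // 1-based centroids for R
      cc.push_back(sc / n + 1.0);
      sz.push_back(n);
    }
  }
  NumericMatrix cent(next, 2);
  for (int k = 0; k < next; ++k) { cent(k, 0) = cr[k]; cent(k, 1) = cc[k]; }
  colnames(cent) = CharacterVector::create("row", "col");
  return List::create(_["labels"] = labels, _["count"] = next,
                      _["centroids"] = cent, _["sizes"] = wrap(sz));
}
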