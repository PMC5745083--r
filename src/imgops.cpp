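#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// 8-connected neighbour offsets.
static const int DR[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

// Label 8-connected components of a logical matrix. Background = 0.
// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerMatrix cpp_label_components(const LogicalMatrix& mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  stack.reserve(256);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c)) continue;
      ++next;
      stack.push_back(r + c * nr);
      lab(r, c) = next;
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int cr = idx % nr, cc = idx / nr;
        for (int k = 0; k < 8; ++k) {
          int r2 = cr + DR[k], c2 = cc + DC[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) && !lab(r2, c2)) {
            lab(r2, c2) = next;
            stack.push_back(r2 + c2 * nr);
          }
        }
      }
    }
  }
  return lab;
}

// Hysteresis: keep weak pixels 8-connected (transitively) to a strong pixel.
// [[Rcpp::export(name = ".cpp_hysteresis")]]
LogicalMatrix cpp_hysteresis(const LogicalMatrix& strong,
                             const LogicalMatrix& weak) {
  int nr = strong.nrow(), nc = strong.ncol();
  LogicalMatrix out(nr, nc);
  std::vector<int> stack;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (strong(r, c)) { out(r, c) = true; stack.push_back(r + c * nr); }
  while (!stack.empty()) {
    int idx = stack.back(); stack.pop_back();
    int cr = idx % nr, cc = idx / nr;
    for (int k = 0; k < 8; ++k) {
      int r2 = cr + DR[k], c2 = cc + DC[k];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      if (weak(r2, c2) && !out(r2, c2)) {
        out(r2, c2) = true;
        stack.push_back(r2 + c2 * nr);
      }
    }
  }
  return out;
}

// Marker-controlled watershed by priority flooding. Pixels flood in order of
// decreasing image intensity (bright cell cores first, valleys last), each
// taking the label of the neighbour that claimed it. Pixels outside `mask`
// stay 0. `markers` holds positive seed labels, 0 elsewhere.
// [[Rcpp::export(name = ".cpp_watershed")]]
IntegerMatrix cpp_watershed(const NumericMatrix& img,
                            const IntegerMatrix& markers,
                            const LogicalMatrix& mask) {
  int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix lab(nr, nc);
  // Max-heap on intensity; ties broken by insertion order for determinism.
  typedef std::pair<double, std::pair<long, int> > Node; // (val, (-order, idx))
  std::priority_queue<Node> pq;
  long order = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (markers(r, c) > 0 && mask(r, c)) {
        lab(r, c) = markers(r, c);
        pq.push(Node(img(r, c), std::make_pair(-(order++), r + c * nr)));
      }
    }
  }
  while (!pq.empty()) {
    int idx = pq.top().second.second; pq.pop();
    int cr = idx % nr, cc = idx / nr;
    int l = lab(cr, cc);
    for (int k = 0; k < 8; ++k) {
      int r2 = cr + DR[k], c2 = cc + DC[k];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      if (!mask(r2, c2) || lab(r2, c2)) continue;
      lab(r2, c2) = l;
      pq.push(Node(img(r2, c2), std::make_pair(-(order++), r2 + c2 * nr)));
    }
  }
  return lab;
}
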