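#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labeling by iterative flood fill.
// connectivity: 4 (edge-adjacent) or 8 (edge- or corner-adjacent).
// Returns an integer matrix of labels (0 = background, 1..k = components,
// numbered in raster order of their first pixel).
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerMatrix label_components_cpp(IntegerMatrix mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nn = (connectivity == 8) ? 8 : 4;
  std::vector<int> stack;
  int next = 0;
  // column-major scan matches R's raster order for reproducible numbering
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (mask(r, c) == 0 || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.clear();
      stack.push_back(r + c * H);
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int rr = idx % H, cc = idx / H;
        for (int k = 0; k < nn; ++k) {
          int r2 = rr + dr8[k], c2 = cc + dc8[k];
          if (r2 < 0 || r2 >= H || c2 < 0 || c2 >= W) continue;
          if (mask(r2, c2) != 0 && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            stack.push_back(r2 + c2 * H);
          }
        }
      }
    }
  }
  return lab;
}

// Zhang-Suen thinning. Classic two-subiteration scheme; deletions within a
// subiteration are applied simultaneously. Pixels outside the frame count
// as background.
// [[Rcpp::export(name = ".thin_cpp")]]
IntegerMatrix thin_cpp(IntegerMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix img = clone(mask);
  for (int i = 0; i < H * W; ++i) img[i] = img[i] ? 1 : 0;
  std::vector<int> del;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int step = 0; step < 2; ++step) {
      del.clear();
      for (int c = 0; c < W; ++c) {
        for (int r = 0; r < H; ++r) {
          if (!img(r, c)) continue;
          // neighbours p2..p9 clockwise from north
          auto at = [&](int rr, int cc) -> int {
            return (rr < 0 || rr >= H || cc < 0 || cc >= W) ? 0 : img(rr, cc);
          };
          const int p2 = at(r - 1, c),     p3 = at(r - 1, c + 1);
          const int p4 = at(r, c + 1),     p5 = at(r + 1, c + 1);
          const int p6 = at(r + 1, c),     p7 = at(r + 1, c - 1);
          const int p8 = at(r, c - 1),     p9 = at(r - 1, c - 1);
          const int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          const int seq[9] = {p2, p3, p4, p5, p6, p7, p8, p9, p2};
          int A = 0;
          for (int k = 0; k < 8; ++k)
            if (seq[k] == 0 && seq[k + 1] == 1) ++A;
          if (A != 1) continue;
          if (step == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          del.push_back(r + c * H);
        }
      }
      if (!del.empty()) {
        changed = true;
        for (int idx : del) img[idx] = 0;
      }
    }
  }
  return img;
}
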