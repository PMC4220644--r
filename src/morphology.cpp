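#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labeling of a binary pattern by breadth-first search.
// Returns an integer matrix: 0 = background, components numbered from 1 in
// order of their first (column-major) foreground pixel.
// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(const LogicalMatrix& x, int connectivity) {
  const int nr = x.nrow(), nc = x.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  stack.reserve(256);
  // neighbour offsets: 4-connectivity first, diagonals appended for 8
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nn = (connectivity == 8) ? 8 : 4;
  int next = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!x(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.push_back(r + c * nr);
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int cr = idx % nr, cc2 = idx / nr;
        for (int k = 0; k < nn; ++k) {
          int r2 = cr + dr8[k], c2 = cc2 + dc8[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (x(r2, c2) && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            stack.push_back(r2 + c2 * nr);
          }
        }
      }
    }
  }
  return lab;
}

static inline int getpix(const std::vector<char>& v, int nr, int nc, int r, int c) {
  if (r < 0 || r >= nr || c < 0 || c >= nc) return 0;
  return v[r + c * nr];
}

static inline void neighbours(const std::vector<char>& img, int nr, int nc,
                              int r, int c, int p[8]) {
  // p2..p9 clockwise from north
  p[0] = getpix(img, nr, nc, r - 1, c);
  p[1] = getpix(img, nr, nc, r - 1, c + 1);
  p[2] = getpix(img, nr, nc, r, c + 1);
  p[3] = getpix(img, nr, nc, r + 1, c + 1);
  p[4] = getpix(img, nr, nc, r + 1, c);
  p[5] = getpix(img, nr, nc, r + 1, c - 1);
  p[6] = getpix(img, nr, nc, r, c - 1);
  p[7] = getpix(img, nr, nc, r - 1, c - 1);
}

static inline int transitions(const int p[8]) {
  int A = 0;
  for (int k = 0; k < 8; ++k)
    if (p[k] == 0 && p[(k + 1) % 8] == 1) ++A;
  return A;
}

// Zhang-Suen iterative thinning. Candidates of each sub-iteration are
// selected on the frozen image (as in the parallel formulation) but deleted
// one at a time with the local topology conditions (A == 1, B >= 2)
// re-checked on the current image: the pure parallel variant can annihilate
// a 2x2 component outright, whereas every deletion here is individually
// safe, so connected components are preserved and the result is idempotent.
// [[Rcpp::export(name = ".thin_pattern")]]
LogicalMatrix thin_pattern(const LogicalMatrix& x) {
  const int nr = x.nrow(), nc = x.ncol();
  std::vector<char> img(nr * nc);
  for (int i = 0; i < nr * nc; ++i) img[i] = x[i] ? 1 : 0;
  std::vector<int> cand;
  int p[8];

  bool changed = true;
  while (changed) {
    changed = false;
    for (int sub = 0; sub < 2; ++sub) {
      cand.clear();
      for (int c = 0; c < nc; ++c) {
        for (int r = 0; r < nr; ++r) {
          if (!img[r + c * nr]) continue;
          neighbours(img, nr, nc, r, c, p);
          int B = p[0] + p[1] + p[2] + p[3] + p[4] + p[5] + p[6] + p[7];
          if (B < 2 || B > 6) continue;
          if (transitions(p) != 1) continue;
          // p2 p4 p6 p8 = p[0] p[2] p[4] p[6]
          if (sub == 0) {
            if (p[0] * p[2] * p[4] != 0 || p[2] * p[4] * p[6] != 0) continue;
          } else {
            if (p[0] * p[2] * p[6] != 0 || p[0] * p[4] * p[6] != 0) continue;
          }
          cand.push_back(r + c * nr);
        }
      }
      for (size_t k = 0; k < cand.size(); ++k) {
        int idx = cand[k];
        int r = idx % nr, c = idx / nr;
        neighbours(img, nr, nc, r, c, p);
        int B = p[0] + p[1] + p[2] + p[3] + p[4] + p[5] + p[6] + p[7];
        if (B < 2 || transitions(p) != 1) continue;
        img[idx] = 0;
        changed = true;
      }
    }
  }
  LogicalMatrix out(nr, nc);
  for (int i = 0; i < nr * nc; ++i) out[i] = img[i] != 0;
  return out;
}
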