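#include <Rcpp.h>
#include <vector>
#include <utility>

using namespace Rcpp;

// Pixels outside the matrix are background throughout.

static inline int px(const std::vector<int>& m, int nr, int nc, int r, int c) {
  if (r < 0 || c < 0 || r >= nr || c >= nc) return 0;
  return m[(size_t)c * nr + r];
}

// Zhang-Suen thinning of a binary mask (column-major, nrow x ncol).
// Deterministic; preserves 8-connectivity of each foreground component.
// [[Rcpp::export(name = ".cpp_thin")]]
IntegerMatrix cpp_thin(IntegerMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  std::vector<int> m(mask.begin(), mask.end());
  for (auto& v : m) v = v != 0 ? 1 : 0;

  std::vector<std::pair<int,int> > kill;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int sub = 0; sub < 2; ++sub) {
      kill.clear();
      for (int c = 0; c < nc; ++c) {
        for (int r = 0; r < nr; ++r) {
          if (!m[(size_t)c * nr + r]) continue;
          // neighbors clockwise from north: p2..p9
          int p2 = px(m, nr, nc, r - 1, c);
          int p3 = px(m, nr, nc, r - 1, c + 1);
          int p4 = px(m, nr, nc, r,     c + 1);
          int p5 = px(m, nr, nc, r + 1, c + 1);
          int p6 = px(m, nr, nc, r + 1, c);
          int p7 = px(m, nr, nc, r + 1, c - 1);
          int p8 = px(m, nr, nc, r,     c - 1);
          int p9 = px(m, nr, nc, r - 1, c - 1);
          int bp = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (bp < 2 || bp > 6) continue;
          int ap = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                   (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                   (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                   (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (ap != 1) continue;
          if (sub == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          kill.push_back(std::make_pair(r, c));
        }
      }
      if (!kill.empty()) {
        changed = true;
        for (size_t i = 0; i < kill.size(); ++i)
          m[(size_t)kill[i].second * nr + kill[i].first] = 0;
      }
    }
  }
  IntegerMatrix out(nr, nc);
  std::copy(m.begin(), m.end(), out.begin());
  return out;
}

// Yokoi connectivity number for 8-connectivity: 1 means the pixel is
// simple (its removal preserves local connectivity).
static inline int yokoi8(const std::vector<int>& m, int nr, int nc,
                         int r, int c) {
  // x1..x8 = E, NE, N, NW, W, SW, S, SE (cyclic)
  int x[10];
  x[1] = px(m, nr, nc, r,     c + 1);
  x[2] = px(m, nr, nc, r - 1, c + 1);
  x[3] = px(m, nr, nc, r - 1, c);
  x[4] = px(m, nr, nc, r - 1, c - 1);
  x[5] = px(m, nr, nc, r,     c - 1);
  x[6] = px(m, nr, nc, r + 1, c - 1);
  x[7] = px(m, nr, nc, r + 1, c);
  x[8] = px(m, nr, nc, r + 1, c + 1);
  x[9] = x[1];
  int n = 0;
  for (int k = 1; k <= 7; k += 2) {
    int xb  = 1 - x[k];
    int xb1 = 1 - x[k + 1];
    int xb2 = 1 - x[(k + 2 <= 8) ? k + 2 : 1];
    n += xb - xb * xb1 * xb2;
  }
  return n;
}

// Reduce a thinned skeleton to minimal form: sequentially (raster order,
// deterministic) delete non-endpoint pixels whose removal preserves
// connectivity. Dissolves staircase elbows and 2x2 blocks that Zhang-Suen
// leaves behind, so junction detection reflects true branch points only.
// [[Rcpp::export(name = ".cpp_skel_cleanup")]]
IntegerMatrix cpp_skel_cleanup(IntegerMatrix skel) {
  int nr = skel.nrow(), nc = skel.ncol();
  std::vector<int> m(skel.begin(), skel.end());
  for (auto& v : m) v = v != 0 ? 1 : 0;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int c = 0; c < nc; ++c) {
      for (int r = 0; r < nr; ++r) {
        if (!m[(size_t)c * nr + r]) continue;
        int deg = 0;
        for (int dc = -1; dc <= 1; ++dc)
          for (int dr = -1; dr <= 1; ++dr) {
            if (dr == 0 && dc == 0) continue;
            deg += px(m, nr, nc, r + dr, c + dc);
          }
        if (deg < 2) continue;                 // keep endpoints
        if (yokoi8(m, nr, nc, r, c) == 1) {
          m[(size_t)c * nr + r] = 0;
          changed = true;
        }
      }
    }
  }
  IntegerMatrix out(nr, nc);
  std::copy(m.begin(), m.end(), out.begin());
  return out;
}

// 8-connected component labeling; labels 1..k in raster (column-major) order
// of each component's first-seen pixel.
// [[Rcpp::export(name = ".cpp_label8")]]
IntegerMatrix cpp_label8(IntegerMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<std::pair<int,int> > stack;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (mask(r, c) == 0 || lab(r, c) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(std::make_pair(r, c));
      lab(r, c) = next;
      while (!stack.empty()) {
        std::pair<int,int> p = stack.back();
        stack.pop_back();
        for (int dc = -1; dc <= 1; ++dc) {
          for (int dr = -1; dr <= 1; ++dr) {
            if (dr == 0 && dc == 0) continue;
            int rr = p.first + dr, cc = p.second + dc;
            if (rr < 0 || cc < 0 || rr >= nr || cc >= nc) continue;
            if (mask(rr, cc) != 0 && lab(rr, cc) == 0) {
              lab(rr, cc) = next;
              stack.push_back(std::make_pair(rr, cc));
            }
          }
        }
      }
    }
  }
  return lab;
}

// Count of foreground 8-neighbors for every foreground pixel (0 elsewhere).
// [[Rcpp::export(name = ".cpp_neighbor_count")]]
IntegerMatrix cpp_neighbor_count(IntegerMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (mask(r, c) == 0) continue;
      int n = 0;
      for (int dc = -1; dc <= 1; ++dc)
        for (int dr = -1; dr <= 1; ++dr) {
          if (dr == 0 && dc == 0) continue;
          int rr = r + dr, cc = c + dc;
          if (rr < 0 || cc < 0 || rr >= nr || cc >= nc) continue;
          if (mask(rr, cc) != 0) ++n;
        }
      out(r, c) = n;
    }
  }
  return out;
}
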