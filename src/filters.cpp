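#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <queue>
using namespace Rcpp;

// reflect index into [0, n-1], edge pixel repeated: -1 -> 0, n -> n-1
static inline int reflect(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// [[Rcpp::export(name = ".median_filter_cpp")]]
NumericMatrix median_filter_cpp(NumericMatrix img, int kernel) {
  int nr = img.nrow(), nc = img.ncol();
  int h = kernel / 2, k2 = kernel * kernel;
  NumericMatrix out(nr, nc);
  std::vector<double> buf(k2);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int idx = 0;
      for (int dc = -h; dc <= h; ++dc) {
        int cc = reflect(c + dc, nc);
        for (int dr = -h; dr <= h; ++dr) {
          buf[idx++] = img(reflect(r + dr, nr), cc);
        }
      }
      std::nth_element(buf.begin(), buf.begin() + k2 / 2, buf.end());
      out(r, c) = buf[k2 / 2];
    }
  }
  return out;
}

// 8-connected foreground labeling; labels 1..n in scan order
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerMatrix label_components_cpp(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::queue<std::pair<int,int> > q;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c)) continue;
      lab(r, c) = ++next;
      q.push(std::make_pair(r, c));
      while (!q.empty()) {
        std::pair<int,int> p = q.front(); q.pop();
        for (int dr = -1; dr <= 1; ++dr) {
          for (int dc = -1; dc <= 1; ++dc) {
            int rr = p.first + dr, cc = p.second + dc;
            if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
            if (mask(rr, cc) && !lab(rr, cc)) {
              lab(rr, cc) = next;
              q.push(std::make_pair(rr, cc));
            }
          }
        }
      }
    }
  }
  return lab;
}

// fill background regions not 4-connected to the image border
// [[Rcpp::export(name = ".fill_holes_cpp")]]
LogicalMatrix fill_holes_cpp(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix reach(nr, nc);  // background reachable from border
  std::queue<std::pair<int,int> > q;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (r == 0 || r == nr - 1 || c == 0 || c == nc - 1) {
        if (!mask(r, c) && !reach(r, c)) {
          reach(r, c) = true;
          q.push(std::make_pair(r, c));
        }
      }
    }
  }
  const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
  while (!q.empty()) {
    std::pair<int,int> p = q.front(); q.pop();
    for (int i = 0; i < 4; ++i) {
      int rr = p.first + dr[i], cc = p.second + dc[i];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (!mask(rr, cc) && !reach(rr, cc)) {
        reach(rr, cc) = true;
        q.push(std::make_pair(rr, cc));
      }
    }
  }
  LogicalMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      out(r, c) = mask(r, c) || !reach(r, c);
  return out;
}
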