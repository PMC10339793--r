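// Cell-binned k-nearest-neighbor search and connectivity check for the
// surface grid.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// [[Rcpp::export(name = ".cppKnn")]]
IntegerMatrix cppKnn(NumericMatrix pts, int k) {
  int n = pts.nrow();
  if (k >= n) stop("k must be smaller than the number of points");
  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) { lo[d] = R_PosInf; hi[d] = R_NegInf; }
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      lo[d] = std::min(lo[d], pts(i,d));
      hi[d] = std::max(hi[d], pts(i,d));
    }
  double ext = std::max({hi[0]-lo[0], hi[1]-lo[1], hi[2]-lo[2]});
  // surface point set: ~n points on area ~ext^2; cell ~ 3x mean spacing
  double cell = 3.0 * ext / std::sqrt(static_cast<double>(n));
  int nc[3];
  for (int d = 0; d < 3; ++d) {
    nc[d] = std::max(1, static_cast<int>((hi[d]-lo[d]) / cell) + 1);
  }
  auto cellOf = [&](int i, int* c) {
    for (int d = 0; d < 3; ++d) {
      c[d] = static_cast<int>((pts(i,d) - lo[d]) / cell);
      if (c[d] >= nc[d]) c[d] = nc[d]-1;
    }
  };
  std::vector<std::vector<int>> bins(
      static_cast<size_t>(nc[0]) * nc[1] * nc[2]);
  auto binIdx = [&](const int* c) {
    return (static_cast<size_t>(c[0]) * nc[1] + c[1]) * nc[2] + c[2];
  };
  for (int i = 0; i < n; ++i) {
    int c[3]; cellOf(i, c);
    bins[binIdx(c)].push_back(i);
  }
  IntegerMatrix out(n, k);
  std::vector<std::pair<double,int>> cand;
  for (int i = 0; i < n; ++i) {
    int c[3]; cellOf(i, c);
    int ring = 1;
    for (;;) {
      cand.clear();
      for (int a = std::max(0, c[0]-ring);
           a <= std::min(nc[0]-1, c[0]+ring); ++a)
        for (int b = std::max(0, c[1]-ring);
             b <= std::min(nc[1]-1, c[1]+ring); ++b)
          for (int d = std::max(0, c[2]-ring);
               d <= std::min(nc[2]-1, c[2]+ring); ++d) {
            int cc[3] = {a, b, d};
            for (int j : bins[binIdx(cc)]) {
              if (j == i) continue;
              double dx = pts(i,0)-pts(j,0), dy = pts(i,1)-pts(j,1),
                     dz = pts(i,2)-pts(j,2);
              cand.emplace_back(dx*dx + dy*dy + dz*dz, j);
            }
          }
      // neighbors beyond ring*cell cannot beat the k-th candidate only if
      // we have k candidates within ring*cell
      if (static_cast<int>(cand.size()) >= k) {
        std::partial_sort(cand.begin(), cand.begin() + k, cand.end());
        double rk = std::sqrt(cand[k-1].first);
        if (rk <= ring * cell || ring >= std::max({nc[0],nc[1],nc[2]}))
          break;
      } else if (ring >= std::max({nc[0], nc[1], nc[2]})) {
        stop("knn: not enough candidates");
      }
      ++ring;
    }
    for (int j = 0; j < k; ++j) out(i, j) = cand[j].second + 1;  // 1-based
  }
  return out;
}

// [[Rcpp::export(name = ".cppComponents")]]
IntegerVector cppComponents(IntegerVector adjIdx, IntegerVector adjPtr) {
  int n = adjPtr.size() - 1;
  IntegerVector comp(n, 0);
  std::vector<int> stack;
  int nc = 0;
  for (int s = 0; s < n; ++s) {
    if (comp[s]) continue;
    ++nc;
    stack.push_back(s);
    comp[s] = nc;
    while (!stack.empty()) {
      int i = stack.back(); stack.pop_back();
      for (int p = adjPtr[i]; p < adjPtr[i+1]; ++p) {
        int j = adjIdx[p];
        if (!comp[j]) { comp[j] = nc; stack.push_back(j); }
      }
    }
  }
  return comp;
}
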