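#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <utility>
using namespace Rcpp;

// k-nearest-neighbour search over an N x 3 coordinate matrix.  Self is
// excluded; ties in squared distance are broken by ascending atom index
// (0-based internally, 1-based in the result).  Rows beyond the number of
// available neighbours are flagged in `sink` with index 0 and distance 0.
// [[Rcpp::export]]
List knn_cpp(NumericMatrix coords, int k) {
  const int n = coords.nrow();
  IntegerMatrix idx(n, k);
  NumericMatrix dist(n, k);
  LogicalMatrix sink(n, k);
  std::vector<std::pair<double, int> > cand(n > 0 ? n : 1);
  for (int i = 0; i < n; ++i) {
    int m = 0;
    const double xi = coords(i, 0), yi = coords(i, 1), zi = coords(i, 2);
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double dx = coords(j, 0) - xi;
      const double dy = coords(j, 1) - yi;
      const double dz = coords(j, 2) - zi;
      cand[m++] = std::make_pair(dx * dx + dy * dy + dz * dz, j);
    }
    const int take = std::min(k, m);
    std::partial_sort(cand.begin(), cand.begin() + take, cand.begin() + m);
    for (int s = 0; s < k; ++s) {
      if (s < take) {
        idx(i, s) = cand[s].second + 1;
        dist(i, s) = std::sqrt(cand[s].first);
        sink(i, s) = false;
      } else {
        idx(i, s) = 0;
        dist(i, s) = 0.0;
        sink(i, s) = true;
      }
    }
  }
  return List::create(_["idx"] = idx, _["dist"] = dist, _["sink"] = sink);
}
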