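#include <Rcpp.h>
#include <unordered_set>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Weighted Kolmogorov-Smirnov running-sum enrichment score evaluated from
// sorted 1-based hit positions only (O(k) instead of O(N)): the running
// sum is piecewise linear between hits, so its extrema occur just before
// or just at hit positions.  absw holds |score|^weight in rank order; if
// all hit weights are zero the hit increment falls back to uniform 1/k.
static double es_from_positions(const std::vector<int>& pos,
                                const NumericVector& absw, const int n) {
  const int k = (int)pos.size();
  double nr = 0.0;
  for (int i = 0; i < k; ++i) nr += absw[pos[i] - 1];
  const double miss = 1.0 / (double)(n - k);
  double cum = 0.0, maxdev = 0.0, mindev = 0.0;
  for (int i = 0; i < k; ++i) {
    const double w = (nr > 0.0) ? absw[pos[i] - 1] / nr : 1.0 / (double)k;
    const double pre = cum - (double)(pos[i] - 1 - i) * miss;
    if (pre < mindev) mindev = pre;
    cum += w;
    const double post = cum - (double)(pos[i] - 1 - i) * miss;
    if (post > maxdev) maxdev = post;
  }
  // positive side wins ties (tolerance keeps the branch stable under
  // floating-point summation order)
  return (maxdev >= -mindev - 1e-12) ? maxdev : mindev;
}

// [[Rcpp::export]]
double es_stat_cpp(NumericVector absw, IntegerVector hit_pos) {
  std::vector<int> pos(hit_pos.begin(), hit_pos.end());
  std::sort(pos.begin(), pos.end());
  return es_from_positions(pos, absw, absw.size());
}

// Gene-label permutation null: n_perm enrichment scores of random subsets
// of size set_size drawn without replacement (Floyd's algorithm, R RNG so
// results are reproducible under set.seed()).
// [[Rcpp::export]]
NumericVector perm_es_null_cpp(NumericVector absw, int set_size, int n_perm) {
  const int n = absw.size();
  if (set_size < 1 || set_size >= n)
    stop("set_size must be in [1, N-1]");
  if (n_perm < 1) stop("n_perm must be >= 1");
  NumericVector out(n_perm);
  std::vector<int> pos;
  pos.reserve(set_size);
  for (int p = 0; p < n_perm; ++p) {
    std::unordered_set<int> chosen;
    chosen.reserve(set_size * 2);
    for (int j = n - set_size + 1; j <= n; ++j) {
      int t = 1 + (int)(unif_rand() * j);
      if (t > j) t = j;
      if (chosen.count(t)) chosen.insert(j); else chosen.insert(t);
    }
    pos.assign(chosen.begin(), chosen.end());
    std::sort(pos.begin(), pos.end());
    out[p] = es_from_positions(pos, absw, n);
  }
  return out;
}
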