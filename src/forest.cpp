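// Regression random forest with held-out permutation importance.
//
// Differences from a textbook forest, all deliberate:
//  * per-tree samples are drawn WITHOUT replacement (a small subsample,
//    typically ceil(sqrt(x)) of x samples), so every tree has a large
//    held-out set on which permutation importance is measured;
//  * all randomness is keyed by hashes of (seed, tree index, node path,
//    column id string), never by column position, so permuting the columns
//    of the design matrix permutes the importance output identically.
//
// Importance contribution of locus j in tree t:
//   (held-out MSE with column j permuted) - (held-out MSE unpermuted);
// columns not used by tree t contribute exactly 0.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97f4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

struct Rng {
  uint64_t state;
  explicit Rng(uint64_t seed) : state(seed) {}
  uint64_t next() {
    state += 0x9E3779B97f4A7C15ULL;
    uint64_t z = state;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform integer in [0, n), n > 0
  uint64_t below(uint64_t n) {
    return (uint64_t)(((__uint128_t)next() * (__uint128_t)n) >> 64);
  }
};

static inline uint64_t fnv1a64(const char* s) {
  uint64_t h = 1469598103934665603ULL;
  while (*s) {
    h ^= (unsigned char)(*s++);
    h *= 1099511628211ULL;
  }
  return h;
}

namespace {

struct Tree {
  std::vector<int> feat;       // -1 for leaf
  std::vector<double> thr;
  std::vector<double> pred;
  std::vector<int> left, right;
  int add_node() {
    feat.push_back(-1); thr.push_back(0.0); pred.push_back(0.0);
    left.push_back(-1); right.push_back(-1);
    return (int)feat.size() - 1;
  }
};

struct Builder {
  const NumericMatrix& X;
  const NumericVector& y;
  const std::vector<uint64_t>& colkey;
  int mtry, min_node;
  Tree tree;
  std::vector<char> used;      // per-column flag

  Builder(const NumericMatrix& X_, const NumericVector& y_,
          const std::vector<uint64_t>& ck, int mtry_, int min_node_)
    : X(X_), y(y_), colkey(ck), mtry(mtry_), min_node(min_node_),
      used(X_.ncol(), 0) {}

  int build(std::vector<int>& idx, uint64_t path_hash) {
    int node = tree.add_node();
    const int n = (int)idx.size();
    double sum = 0.0;
    for (int i : idx) sum += y[i];
    const double mean = sum / n;
    tree.pred[node] = mean;

    if (n <= min_node) return node;
    bool y_const = true;
    for (int i : idx) if (y[i] != y[idx[0]]) { y_const = false; break; }
    if (y_const) return node;

    // candidate columns: mtry smallest id-keyed hash priorities
    const int p = X.ncol();
    std::vector<std::pair<uint64_t, int> > prio(p);
    for (int j = 0; j < p; ++j)
      prio[j] = std::make_pair(splitmix64(path_hash ^ colkey[j]), j);
    const int m = std::min(mtry, p);
    std::partial_sort(prio.begin(), prio.begin() + m, prio.end());

    int best_j = -1;
    double best_thr = 0.0, best_gain = 0.0;
    std::vector<std::pair<double, int> > vals(n);
    const double sse_parent_term = sum * sum / n;

    for (int c = 0; c < m; ++c) {
      const int j = prio[c].second;
      for (int k = 0; k < n; ++k)
        vals[k] = std::make_pair(X(idx[k], j), idx[k]);
      std::sort(vals.begin(), vals.end());
      if (vals.front().first == vals.back().first) continue;  // constant
      double lsum = 0.0;
      for (int k = 0; k < n - 1; ++k) {
        lsum += y[vals[k].second];
        if (vals[k].first == vals[k + 1].first) continue;
        const int nl = k + 1, nr = n - nl;
        // maximize decrease in SSE = sumL^2/nL + sumR^2/nR - sum^2/n
        const double rsum = sum - lsum;
        const double gain = lsum * lsum / nl + rsum * rsum / nr - sse_parent_term;
        if (gain > best_gain) {
          best_gain = gain;
          best_j = j;
          best_thr = vals[k].first + (vals[k + 1].first - vals[k].first) / 2.0;
        }
      }
    }
    if (best_j < 0) return node;

    used[best_j] = 1;
    tree.feat[node] = best_j;
    tree.thr[node] = best_thr;
    std::vector<int> lidx, ridx;
    lidx.reserve(n); ridx.reserve(n);
    for (int i : idx)
      (X(i, best_j) <= best_thr ? lidx : ridx).push_back(i);
    const uint64_t hb = path_hash ^ colkey[best_j];
    tree.left[node]  = build(lidx, splitmix64(hb ^ 0x9E2BULL));
    tree.right[node] = build(ridx, splitmix64(hb ^ 0x51C6ULL));
    return node;
  }

  // predict row i, optionally overriding one column's value
  double predict(int i, int override_col, double override_val) const {
    int node = 0;
    while (tree.feat[node] >= 0) {
      const int j = tree.feat[node];
      const double v = (j == override_col) ? override_val : X(i, j);
      node = (v <= tree.thr[node]) ? tree.left[node] : tree.right[node];
    }
    return tree.pred[node];
  }
};

}  // namespace

// [[Rcpp::export(name = ".rf_importance_cpp")]]
List rf_importance_cpp(NumericMatrix X, NumericVector y, CharacterVector col_ids,
                       int n_trees, int mtry, int samples_per_tree,
                       int min_node_size, double seed) {
  const int x = X.nrow(), p = X.ncol();
  if (y.size() != x) stop("length(y) must equal nrow(X)");
  if (col_ids.size() != p) stop("one column id per column required");
  if (samples_per_tree < 2 || samples_per_tree > x)
    stop("samples_per_tree out of range");
  if (x - samples_per_tree < 2)
    stop("fewer than 2 held-out samples per tree");

  std::vector<uint64_t> colkey(p);
  for (int j = 0; j < p; ++j)
    colkey[j] = fnv1a64(CHAR(STRING_ELT(col_ids, j)));

  const uint64_t seed64 = splitmix64((uint64_t)(long long)seed ^ 0xD1B54A32D192ED03ULL);
  std::vector<double> sum_imp(p, 0.0), sumsq_imp(p, 0.0);
  std::vector<int> all_idx(x);
  const int n_held = x - samples_per_tree;

  for (int t = 0; t < n_trees; ++t) {
    const uint64_t tree_seed = splitmix64(seed64 ^ splitmix64((uint64_t)(t + 1)));

    // subsample without replacement (partial Fisher-Yates)
    for (int i = 0; i < x; ++i) all_idx[i] = i;
    Rng samp_rng(splitmix64(tree_seed ^ 0xBA66ULL));
    for (int i = 0; i < samples_per_tree; ++i) {
      const int k = i + (int)samp_rng.below((uint64_t)(x - i));
      std::swap(all_idx[i], all_idx[k]);
    }
    std::vector<int> in_bag(all_idx.begin(), all_idx.begin() + samples_per_tree);
    std::vector<int> held(all_idx.begin() + samples_per_tree, all_idx.end());
    // keep held-out order independent of the draw
    std::sort(held.begin(), held.end());

    Builder b(X, y, colkey, mtry, min_node_size);
    b.build(in_bag, splitmix64(tree_seed ^ 0x7EEE5ULL));

    double mse0 = 0.0;
    for (int i : held) {
      const double e = y[i] - b.predict(i, -1, 0.0);
      mse0 += e * e;
    }
    mse0 /= n_held;

    for (int j = 0; j < p; ++j) {
      if (!b.used[j]) continue;  // contribution exactly 0
      // permute held-out values of column j (id-keyed stream)
      std::vector<double> perm(n_held);
      for (int k = 0; k < n_held; ++k) perm[k] = X(held[k], j);
      Rng perm_rng(splitmix64(tree_seed ^ colkey[j] ^ 0xC0FFEEULL));
      for (int k = n_held - 1; k > 0; --k) {
        const int r = (int)perm_rng.below((uint64_t)(k + 1));
        std::swap(perm[k], perm[r]);
      }
      double msep = 0.0;
      for (int k = 0; k < n_held; ++k) {
        const double e = y[held[k]] - b.predict(held[k], j, perm[k]);
        msep += e * e;
      }
      msep /= n_held;
      const double imp = msep - mse0;
      sum_imp[j] += imp;
      sumsq_imp[j] += imp * imp;
    }
  }

  NumericVector mean_imp(p), sd_imp(p);
  for (int j = 0; j < p; ++j) {
    const double mu = sum_imp[j] / n_trees;
    mean_imp[j] = mu;
    double ss = sumsq_imp[j] - n_trees * mu * mu;
    if (ss < 0) ss = 0;
    sd_imp[j] = (n_trees > 1) ? std::sqrt(ss / (n_trees - 1)) : 0.0;
  }
  mean_imp.names() = col_ids;
  sd_imp.names() = col_ids;
  return List::create(_["mean"] = mean_imp, _["sd"] = sd_imp,
                      _["n_trees"] = n_trees);
}
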