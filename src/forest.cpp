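#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Deterministic, platform-independent RNG (splitmix64).  Tree k of a forest
// gets its own stream keyed by (seed, k) so results do not depend on the
// order in which trees are materialized.
struct SplitMix {
  uint64_t state;
  explicit SplitMix(uint64_t s) : state(s) {}
  uint64_t next() {
    uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform integer in [0, n), rejection-sampled to avoid modulo bias
  uint64_t bounded(uint64_t n) {
    if (n <= 1) return 0;
    uint64_t lim = UINT64_MAX - UINT64_MAX % n;
    uint64_t r;
    do { r = next(); } while (r >= lim);
    return r % n;
  }
};

static uint64_t mix64(uint64_t x) {
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static uint64_t tree_seed(uint64_t seed, int k) {
  return mix64(mix64(seed + 0x9E3779B97F4A7C15ULL) ^ (uint64_t)(k + 1) * 0xD1B54A32D192ED03ULL);
}

// Splits whose weighted child impurities differ by no more than this are
// treated as tied and resolved by (feature index, threshold).
static const double TIE_EPS = 1e-12;

static double gini_of(const std::vector<int>& cnt, int n) {
  double g = 1.0;
  for (size_t j = 0; j < cnt.size(); ++j) {
    double p = (double)cnt[j] / n;
    g -= p * p;
  }
  return g;
}

struct SplitRes {
  bool ok;
  int feature;       // 0-based column of X
  double threshold;  // x <= threshold goes left
  double gini;       // weighted child impurity of the split
};

// Exhaustive scan over candidate features and midpoint thresholds, minimizing
// the weighted child Gini; ties broken by lower feature index, then lower
// threshold.
static SplitRes best_split_core(const NumericMatrix& X, const IntegerVector& y,
                                const std::vector<int>& idx,
                                const std::vector<int>& cand, int nclass) {
  SplitRes best; best.ok = false; best.feature = -1;
  best.threshold = 0.0; best.gini = R_PosInf;
  int n = (int)idx.size();
  std::vector<std::pair<double,int> > vals(n);
  std::vector<int> lc(nclass), rc(nclass);
  for (size_t ci = 0; ci < cand.size(); ++ci) {
    int f = cand[ci];
    for (int i = 0; i < n; ++i)
      vals[i] = std::make_pair(X(idx[i], f), y[idx[i]]);
    std::sort(vals.begin(), vals.end());
    if (vals[0].first == vals[n - 1].first) continue;  // constant in node
    std::fill(lc.begin(), lc.end(), 0);
    std::fill(rc.begin(), rc.end(), 0);
    for (int i = 0; i < n; ++i) rc[vals[i].second]++;
    for (int i = 0; i < n - 1; ++i) {
      lc[vals[i].second]++;
      rc[vals[i].second]--;
      if (vals[i + 1].first <= vals[i].first) continue;  // not a cut point
      int nl = i + 1, nr = n - nl;
      double g = ((double)nl / n) * gini_of(lc, nl) +
                 ((double)nr / n) * gini_of(rc, nr);
      double thr = (vals[i].first + vals[i + 1].first) / 2.0;
      bool take = false;
      if (!best.ok || g < best.gini - TIE_EPS) take = true;
      else if (std::fabs(g - best.gini) <= TIE_EPS) {
        if (f < best.feature ||
            (f == best.feature && thr < best.threshold)) take = true;
      }
      if (take) {
        best.ok = true; best.feature = f; best.threshold = thr; best.gini = g;
      }
    }
  }
  return best;
}

struct TreeBuf {
  std::vector<int> feature;        // -1 for leaf
  std::vector<double> threshold;
  std::vector<int> left_child, right_child;  // -1 for leaf
  std::vector<int> pred;           // majority class (0-based), ties -> lowest
  std::vector<int> n_node;
  std::vector<double> decrease;    // recorded Gini decrease at internal nodes
};

static int majority_class(const std::vector<int>& cnt) {
  int best = 0;
  for (size_t j = 1; j < cnt.size(); ++j)
    if (cnt[j] > cnt[best]) best = (int)j;
  return best;
}

// Partial Fisher-Yates: first k entries of pool become a uniform
// without-replacement draw; the pool stays a permutation of itself so
// subsequent node-level draws remain uniform.
static void draw_k(std::vector<int>& pool, int k, SplitMix& rng) {
  int n = (int)pool.size();
  for (int i = 0; i < k; ++i) {
    int j = i + (int)rng.bounded((uint64_t)(n - i));
    std::swap(pool[i], pool[j]);
  }
}

static int grow_node(const NumericMatrix& X, const IntegerVector& y, int nclass,
                     std::vector<int>& idx, int n_root, int n_min,
                     std::vector<int>& pool_s, std::vector<int>& pool_w,
                     int mtry_s, int mtry_w, SplitMix& rng,
                     TreeBuf& tb, std::vector<double>& imp) {
  int n = (int)idx.size();
  std::vector<int> cnt(nclass, 0);
  for (int i = 0; i < n; ++i) cnt[y[idx[i]]]++;
  int nmaj = *std::max_element(cnt.begin(), cnt.end());
  bool leaf = (n <= n_min) || (nmaj == n);
  SplitRes sp; sp.ok = false;
  if (!leaf) {
    std::vector<int> cand;
    cand.reserve(mtry_s + mtry_w);
    if (mtry_s > 0) {
      draw_k(pool_s, mtry_s, rng);
      cand.insert(cand.end(), pool_s.begin(), pool_s.begin() + mtry_s);
    }
    if (mtry_w > 0) {
      draw_k(pool_w, mtry_w, rng);
      cand.insert(cand.end(), pool_w.begin(), pool_w.begin() + mtry_w);
    }
    sp = best_split_core(X, y, idx, cand, nclass);
    if (!sp.ok) leaf = true;
  }
  int me = (int)tb.feature.size();
  tb.feature.push_back(-1); tb.threshold.push_back(0.0);
  tb.left_child.push_back(-1); tb.right_child.push_back(-1);
  tb.pred.push_back(majority_class(cnt));
  tb.n_node.push_back(n); tb.decrease.push_back(0.0);
  if (leaf) return me;

  std::vector<int> lidx, ridx;
  for (int i = 0; i < n; ++i) {
    if (X(idx[i], sp.feature) <= sp.threshold) lidx.push_back(idx[i]);
    else ridx.push_back(idx[i]);
  }
  double dec = ((double)n / n_root) * (gini_of(cnt, n) - sp.gini);
  if (dec < 0) dec = 0;  // guard fp underflow; a chosen split never worsens
  tb.feature[me] = sp.feature;
  tb.threshold[me] = sp.threshold;
  tb.decrease[me] = dec;
  imp[sp.feature] += dec;
  { std::vector<int>().swap(idx); }  // free before recursing
  int l = grow_node(X, y, nclass, lidx, n_root, n_min, pool_s, pool_w,
                    mtry_s, mtry_w, rng, tb, imp);
  int r = grow_node(X, y, nclass, ridx, n_root, n_min, pool_s, pool_w,
                    mtry_s, mtry_w, rng, tb, imp);
  tb.left_child[me] = l;
  tb.right_child[me] = r;
  return me;
}

// [[Rcpp::export]]
List cpp_fit_forest(NumericMatrix X, IntegerVector y, int nclass, int K,
                    IntegerVector pool_strong, IntegerVector pool_weak,
                    int mtry_s, int mtry_w, int n_min,
                    double seed, bool bootstrap) {
  int N = X.nrow(), M = X.ncol();
  List trees(K), boots(K);
  NumericMatrix importance(K, M);
  std::vector<int> ps0(pool_strong.begin(), pool_strong.end());
  std::vector<int> pw0(pool_weak.begin(), pool_weak.end());
  for (int k = 0; k < K; ++k) {
    SplitMix rng(tree_seed((uint64_t)seed, k));
    std::vector<int> idx(N);
    IntegerVector boot(N);
    if (bootstrap) {
      for (int i = 0; i < N; ++i) {
        idx[i] = (int)rng.bounded((uint64_t)N);
        boot[i] = idx[i] + 1;  // 1-based for R
      }
    } else {
      for (int i = 0; i < N; ++i) { idx[i] = i; boot[i] = i + 1; }
    }
    std::vector<int> ps(ps0), pw(pw0);
    TreeBuf tb;
    std::vector<double> imp(M, 0.0);
    grow_node(X, y, nclass, idx, N, n_min, ps, pw, mtry_s, mtry_w, rng, tb, imp);
    int nn = (int)tb.feature.size();
    IntegerVector feat(nn), lc(nn), rc(nn), pr(nn), nv(nn);
    NumericVector thr(nn), dec(nn);
    for (int i = 0; i < nn; ++i) {
      feat[i] = tb.feature[i]; thr[i] = tb.threshold[i];
      lc[i] = tb.left_child[i]; rc[i] = tb.right_child[i];
      pr[i] = tb.pred[i]; nv[i] = tb.n_node[i]; dec[i] = tb.decrease[i];
    }
    trees[k] = List::create(_["feature"] = feat, _["threshold"] = thr,
                            _["left"] = lc, _["right"] = rc,
                            _["pred"] = pr, _["n_node"] = nv,
                            _["decrease"] = dec);
    boots[k] = boot;
    for (int f = 0; f < M; ++f) importance(k, f) = imp[f];
  }
  return List::create(_["trees"] = trees, _["bootstrap"] = boots,
                      _["importance"] = importance);
}

// [[Rcpp::export]]
IntegerMatrix cpp_predict_trees(List trees, NumericMatrix X) {
  int K = trees.size(), N = X.nrow();
  IntegerMatrix out(N, K);  // 0-based class per tree
  for (int k = 0; k < K; ++k) {
    List t = trees[k];
    IntegerVector feat = t["feature"], lc = t["left"], rc = t["right"],
                  pr = t["pred"];
    NumericVector thr = t["threshold"];
    for (int i = 0; i < N; ++i) {
      int node = 0;
      while (feat[node] >= 0) {
        node = (X(i, feat[node]) <= thr[node]) ? lc[node] : rc[node];
      }
      out(i, k) = pr[node];
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_best_split(NumericMatrix X, IntegerVector y, int nclass,
                    IntegerVector idx, IntegerVector candidates) {
  std::vector<int> ix(idx.begin(), idx.end());
  std::vector<int> cd(candidates.begin(), candidates.end());
  SplitRes sp = best_split_core(X, y, ix, cd, nclass);
  return List::create(_["ok"] = sp.ok, _["feature"] = sp.feature,
                      _["threshold"] = sp.threshold, _["gini"] = sp.gini);
}
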