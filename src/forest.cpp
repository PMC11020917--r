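// CART-based binary classification forest with non-uniform sampling of the
// candidate splitting variables at each node. All randomness goes through
// R's RNG (unif_rand) so results are reproducible under set.seed().
//
// Conventions fixed here and relied on by the R surface and the tests:
//  - candidate draws: successive weighted draws without replacement,
//    renormalizing over the remaining pool after each draw; the unweighted
//    path is a separate routine that indexes the same pool uniformly
//  - split search: thresholds at midpoints of consecutive distinct sorted
//    values; ties in impurity decrease broken by lowest gene index, then
//    lowest threshold (candidates are scanned in ascending index order)
//  - samples with value <= threshold go left
//  - leaf prediction: majority class, exact tie -> class 0
//  - forest prediction: majority vote over trees, exact tie -> class 0

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

// Draw `mtry` distinct indices from `pool` (ascending gene indices).
// Weighted: probability proportional to w[idx], renormalized after each
// draw. Pool order is preserved on removal so that the weighted routine
// with equal weights and the uniform routine consume identical RNG and
// select identical indices.
std::vector<int> draw_weighted(const std::vector<int>& pool,
                               const std::vector<double>& w, int mtry) {
  std::vector<int> rem(pool), out;
  out.reserve(mtry);
  for (int d = 0; d < mtry && !rem.empty(); ++d) {
    double total = 0.0;
    for (int idx : rem) total += w[idx];
    double u = unif_rand() * total, acc = 0.0;
    size_t pick = rem.size() - 1;
    for (size_t j = 0; j < rem.size(); ++j) {
      acc += w[rem[j]];
      if (u <= acc) { pick = j; break; }
    }
    out.push_back(rem[pick]);
    rem.erase(rem.begin() + pick);
  }
  std::sort(out.begin(), out.end());
  return out;
}

std::vector<int> draw_uniform(const std::vector<int>& pool, int mtry) {
  std::vector<int> rem(pool), out;
  out.reserve(mtry);
  for (int d = 0; d < mtry && !rem.empty(); ++d) {
    size_t pick = (size_t)(unif_rand() * rem.size());
    if (pick >= rem.size()) pick = rem.size() - 1;
    out.push_back(rem[pick]);
    rem.erase(rem.begin() + pick);
  }
  std::sort(out.begin(), out.end());
  return out;
}

struct TreeBuf {
  std::vector<int> split_var, left, right, n0, n1;
  std::vector<double> threshold;
  int add_node(int c0, int c1) {
    split_var.push_back(-1);
    threshold.push_back(NA_REAL);
    left.push_back(-1);
    right.push_back(-1);
    n0.push_back(c0);
    n1.push_back(c1);
    return (int)split_var.size() - 1;
  }
};

struct BestSplit {
  int var = -1;
  double thr = 0.0, dec = 0.0;
  bool found = false;
};

inline double gini_term(double c0, double c1, double n) {
  // n * gini = n - (c0^2 + c1^2) / n
  return n - (c0 * c0 + c1 * c1) / n;
}

// Exhaustive best split over the candidate variables for samples
// smp[from..to). Returns the split maximizing the Gini impurity decrease.
BestSplit best_split(const NumericMatrix& X, const IntegerVector& y,
                     const std::vector<int>& smp, int from, int to,
                     const std::vector<int>& cand, int c0, int c1) {
  BestSplit best;
  const int n = to - from;
  const double parent = gini_term((double)c0, (double)c1, (double)n);
  std::vector<std::pair<double, int>> v(n);
  for (int vi : cand) {
    for (int k = 0; k < n; ++k) {
      int s = smp[from + k];
      v[k] = std::make_pair(X(s, vi), y[s]);
    }
    std::sort(v.begin(), v.end());
    double l0 = 0, l1 = 0;
    for (int k = 0; k < n - 1; ++k) {
      if (v[k].second == 0) l0 += 1; else l1 += 1;
      if (v[k + 1].first <= v[k].first) continue;  // not a distinct boundary
      double nl = l0 + l1, nr = n - nl;
      double dec = parent - gini_term(l0, l1, nl)
                          - gini_term((double)c0 - l0, (double)c1 - l1, nr);
      // dec is n * (impurity decrease); positive scaling preserves argmax
      if (dec > best.dec + 1e-12 * (double)n) {
        best.var = vi;
        best.thr = 0.5 * (v[k].first + v[k + 1].first);
        best.dec = dec;
        best.found = true;
      }
    }
  }
  return best;
}

struct Node { int id, from, to; };

int traverse(const IntegerVector& split_var, const NumericVector& threshold,
             const IntegerVector& left, const IntegerVector& right,
             const NumericMatrix& X, int i, int perm_var, double perm_val) {
  int node = 0;
  while (split_var[node] >= 0) {
    int sv = split_var[node];
    double x = (sv == perm_var) ? perm_val : X(i, sv);
    node = (x <= threshold[node]) ? left[node] : right[node];
  }
  return node;
}

}  // namespace

// [[Rcpp::export]]
List cpp_fit_forest(NumericMatrix X, IntegerVector y, NumericVector prior,
                    int ntree, int mtry, int min_node_size, bool weighted) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> w(prior.begin(), prior.end());
  std::vector<int> pool;
  if (weighted) {
    for (int j = 0; j < p; ++j) if (w[j] > 0) pool.push_back(j);
  } else {
    for (int j = 0; j < p; ++j) pool.push_back(j);
  }
  if (pool.empty()) stop("no genes with positive sampling weight");
  const int m = std::min<int>(mtry, (int)pool.size());

  List trees(ntree);
  for (int t = 0; t < ntree; ++t) {
    // bootstrap of size n, with replacement
    std::vector<int> smp(n);
    std::vector<bool> inbag(n, false);
    for (int i = 0; i < n; ++i) {
      int k = (int)(unif_rand() * n);
      if (k >= n) k = n - 1;
      smp[i] = k;
      inbag[k] = true;
    }
    std::vector<int> boot(smp), oob;
    for (int i = 0; i < n; ++i) if (!inbag[i]) oob.push_back(i);

    TreeBuf tb;
    std::vector<bool> used(p, false);
    std::vector<Node> stack;
    {
      int c0 = 0, c1 = 0;
      for (int i = 0; i < n; ++i) (y[smp[i]] == 0 ? c0 : c1)++;
      int root = tb.add_node(c0, c1);
      stack.push_back({root, 0, n});
    }
    while (!stack.empty()) {
      Node nd = stack.back();
      stack.pop_back();
      int c0 = tb.n0[nd.id], c1 = tb.n1[nd.id], nn = nd.to - nd.from;
      if (nn <= min_node_size || c0 == 0 || c1 == 0 || nn < 2) continue;
      std::vector<int> cand = weighted ? draw_weighted(pool, w, m)
                                       : draw_uniform(pool, m);
      BestSplit bs = best_split(X, y, smp, nd.from, nd.to, cand, c0, c1);
      if (!bs.found) continue;
      // partition: left <- x <= thr (stable, preserves bootstrap order)
      std::vector<int> lft, rgt;
      int l0 = 0, l1 = 0;
      for (int k = nd.from; k < nd.to; ++k) {
        int s = smp[k];
        if (X(s, bs.var) <= bs.thr) {
          lft.push_back(s);
          (y[s] == 0 ? l0 : l1)++;
        } else rgt.push_back(s);
      }
      std::copy(lft.begin(), lft.end(), smp.begin() + nd.from);
      std::copy(rgt.begin(), rgt.end(), smp.begin() + nd.from + lft.size());
      int lid = tb.add_node(l0, l1);
      int rid = tb.add_node(c0 - l0, c1 - l1);
      tb.split_var[nd.id] = bs.var;
      tb.threshold[nd.id] = bs.thr;
      tb.left[nd.id] = lid;
      tb.right[nd.id] = rid;
      used[bs.var] = true;
      int mid = nd.from + (int)lft.size();
      stack.push_back({rid, mid, nd.to});
      stack.push_back({lid, nd.from, mid});
    }
    std::vector<int> used_idx;
    for (int j = 0; j < p; ++j) if (used[j]) used_idx.push_back(j);
    trees[t] = List::create(
        _["split_var"] = wrap(tb.split_var), _["threshold"] = wrap(tb.threshold),
        _["left"] = wrap(tb.left), _["right"] = wrap(tb.right),
        _["n0"] = wrap(tb.n0), _["n1"] = wrap(tb.n1),
        _["boot"] = wrap(boot), _["oob"] = wrap(oob),
        _["used"] = wrap(used_idx));
  }
  return trees;
}

// [[Rcpp::export]]
List cpp_predict_forest(List trees, NumericMatrix X) {
  const int n = X.nrow(), ntree = trees.size();
  IntegerVector votes1(n);
  for (int t = 0; t < ntree; ++t) {
    List tr = trees[t];
    IntegerVector sv = tr["split_var"], lf = tr["left"], rg = tr["right"];
    IntegerVector n0 = tr["n0"], n1 = tr["n1"];
    NumericVector th = tr["threshold"];
    for (int i = 0; i < n; ++i) {
      int leaf = traverse(sv, th, lf, rg, X, i, -1, 0.0);
      if (n1[leaf] > n0[leaf]) votes1[i]++;
    }
  }
  IntegerVector pred(n);
  NumericVector frac(n);
  for (int i = 0; i < n; ++i) {
    frac[i] = (double)votes1[i] / ntree;
    pred[i] = (2 * votes1[i] > ntree) ? 1 : 0;  // tie -> class 0
  }
  return List::create(_["pred"] = pred, _["vote_frac_1"] = frac);
}

// [[Rcpp::export]]
List cpp_permutation_importance(List trees, NumericMatrix X, IntegerVector y) {
  const int p = X.ncol(), ntree = trees.size();
  NumericVector imp(p);
  int n_eff = 0;
  for (int t = 0; t < ntree; ++t) {
    List tr = trees[t];
    IntegerVector oob = tr["oob"];
    const int no = oob.size();
    if (no == 0) continue;
    n_eff++;
    IntegerVector sv = tr["split_var"], lf = tr["left"], rg = tr["right"];
    IntegerVector n0 = tr["n0"], n1 = tr["n1"], used = tr["used"];
    NumericVector th = tr["threshold"];
    double acc = 0.0;
    for (int k = 0; k < no; ++k) {
      int leaf = traverse(sv, th, lf, rg, X, oob[k], -1, 0.0);
      int cls = (n1[leaf] > n0[leaf]) ? 1 : 0;
      if (cls == y[oob[k]]) acc += 1.0;
    }
    acc /= no;
    std::vector<int> perm(no);
    for (int v = 0; v < used.size(); ++v) {
      int var = used[v];
      for (int k = 0; k < no; ++k) perm[k] = k;
      for (int k = no - 1; k > 0; --k) {  // Fisher-Yates
        int j = (int)(unif_rand() * (k + 1));
        if (j > k) j = k;
        std::swap(perm[k], perm[j]);
      }
      double acc_p = 0.0;
      for (int k = 0; k < no; ++k) {
        double pv = X(oob[perm[k]], var);
        int leaf = traverse(sv, th, lf, rg, X, oob[k], var, pv);
        int cls = (n1[leaf] > n0[leaf]) ? 1 : 0;
        if (cls == y[oob[k]]) acc_p += 1.0;
      }
      acc_p /= no;
      imp[var] += acc - acc_p;
    }
  }
  if (n_eff > 0) for (int j = 0; j < p; ++j) imp[j] /= n_eff;
  return List::create(_["importance"] = imp, _["n_oob_trees"] = n_eff);
}

// [[Rcpp::export]]
IntegerMatrix cpp_sample_candidates(NumericVector prior, int mtry, int ndraws,
                                    bool weighted) {
  const int p = prior.size();
  std::vector<double> w(prior.begin(), prior.end());
  std::vector<int> pool;
  if (weighted) {
    for (int j = 0; j < p; ++j) if (w[j] > 0) pool.push_back(j);
  } else {
    for (int j = 0; j < p; ++j) pool.push_back(j);
  }
  if (pool.empty()) stop("no genes with positive sampling weight");
  const int m = std::min<int>(mtry, (int)pool.size());
  IntegerMatrix out(ndraws, m);
  for (int d = 0; d < ndraws; ++d) {
    std::vector<int> got = weighted ? draw_weighted(pool, w, m)
                                    : draw_uniform(pool, m);
    for (int j = 0; j < m; ++j) out(d, j) = got[j] + 1;  // 1-based for R
  }
  return out;
}
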