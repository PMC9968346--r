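// Per-SNP random-forest regressions with split-record harvest.
//
// Each SNP's population allele frequencies are regressed on the
// environmental / spatial predictors by a forest of CART-style regression
// trees (bootstrap resampling, random feature subsets, exhaustive split
// search minimising SSE). Split improvements (SSE reductions) are
// accumulated per predictor into a fixed bin grid along each predictor's
// observed range; out-of-bag predictions give each SNP's R^2. These are the
// raw materials of the cumulative-importance turnover functions.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct Node {
  int pred = -1;        // -1: leaf
  double split = 0.0;
  int left = -1, right = -1;
  double value = 0.0;
};

struct SplitRec {
  int pred;
  double value;
  double improve;
};

// grow one node; returns node index
int grow(std::vector<Node>& nodes, const NumericMatrix& X,
         const std::vector<double>& y, std::vector<int>& idx,
         int lo, int hi, int mtry, int min_node,
         std::vector<SplitRec>& recs) {
  int node_id = (int)nodes.size();
  nodes.push_back(Node());
  int n = hi - lo;
  double sum = 0.0, ss = 0.0;
  for (int k = lo; k < hi; ++k) sum += y[idx[k]];
  double mean = sum / n;
  for (int k = lo; k < hi; ++k) {
    double d = y[idx[k]] - mean;
    ss += d * d;
  }
  nodes[node_id].value = mean;
  if (n <= min_node || ss <= 1e-12) return node_id;

  int p = X.ncol();
  // sample mtry predictors without replacement (partial Fisher-Yates)
  std::vector<int> preds(p);
  for (int j = 0; j < p; ++j) preds[j] = j;
  int m = std::min(mtry, p);
  for (int j = 0; j < m; ++j) {
    int pick = j + (int)(unif_rand() * (p - j));
    if (pick >= p) pick = p - 1;
    std::swap(preds[j], preds[pick]);
  }

  double best_imp = 0.0, best_split = 0.0;
  int best_pred = -1;
  std::vector<std::pair<double, double>> xv(n); // (x, y)
  for (int jj = 0; jj < m; ++jj) {
    int j = preds[jj];
    for (int k = 0; k < n; ++k) {
      int i = idx[lo + k];
      xv[k] = std::make_pair(X(i, j), y[i]);
    }
    std::sort(xv.begin(), xv.end());
    double left_sum = 0.0;
    for (int k = 0; k < n - 1; ++k) {
      left_sum += xv[k].second;
      if (xv[k + 1].first <= xv[k].first) continue; // no gap: not a split point
      int nl = k + 1, nr = n - nl;
      double right_sum = sum - left_sum;
      // SSE reduction = between-group SS of the two children
      double imp = left_sum * left_sum / nl + right_sum * right_sum / nr -
                   sum * sum / n;
      if (imp > best_imp) {
        best_imp = imp;
        best_pred = j;
        best_split = 0.5 * (xv[k].first + xv[k + 1].first);
      }
    }
  }
  if (best_pred < 0) return node_id;

  recs.push_back({best_pred, best_split, best_imp});
  // partition idx[lo, hi) by the split
  int mid = lo;
  for (int k = lo; k < hi; ++k) {
    if (X(idx[k], best_pred) <= best_split) {
      std::swap(idx[k], idx[mid]);
      ++mid;
    }
  }
  nodes[node_id].pred = best_pred;
  nodes[node_id].split = best_split;
  int l = grow(nodes, X, y, idx, lo, mid, mtry, min_node, recs);
  int r = grow(nodes, X, y, idx, mid, hi, mtry, min_node, recs);
  nodes[node_id].left = l;
  nodes[node_id].right = r;
  return node_id;
}

double predict_tree(const std::vector<Node>& nodes, const NumericMatrix& X,
                    int row) {
  int cur = 0;
  while (nodes[cur].pred >= 0) {
    cur = (X(row, nodes[cur].pred) <= nodes[cur].split) ? nodes[cur].left
                                                        : nodes[cur].right;
  }
  return nodes[cur].value;
}

} // namespace

// [[Rcpp::export]]
List snp_forest_cpp(NumericMatrix X, NumericMatrix Y, int n_trees, int mtry,
                    int min_node, List breaks) {
  int n = X.nrow(), p = X.ncol(), S = Y.ncol();
  if (Y.nrow() != n) stop("X and Y must have the same number of rows");
  int nbins = as<NumericVector>(breaks[0]).size() - 1;

  NumericVector r2(S);
  NumericMatrix importance(S, p);
  NumericVector binned(S * p * nbins); // [s + S*(j + p*b)]
  std::vector<std::vector<double>> brk(p);
  for (int j = 0; j < p; ++j) brk[j] = as<std::vector<double>>(breaks[j]);

  RNGScope scope;
  std::vector<int> idx(n), boot(n);
  std::vector<char> inbag(n);
  std::vector<double> y(n), oob_sum(n);
  std::vector<int> oob_cnt(n);
  std::vector<SplitRec> recs;
  std::vector<Node> nodes;

  for (int s = 0; s < S; ++s) {
    for (int i = 0; i < n; ++i) y[i] = Y(i, s);
    std::fill(oob_sum.begin(), oob_sum.end(), 0.0);
    std::fill(oob_cnt.begin(), oob_cnt.end(), 0);
    for (int t = 0; t < n_trees; ++t) {
      std::fill(inbag.begin(), inbag.end(), 0);
      for (int i = 0; i < n; ++i) {
        int b = (int)(unif_rand() * n);
        if (b >= n) b = n - 1;
        boot[i] = b;
        inbag[b] = 1;
      }
      idx = boot;
      recs.clear();
      nodes.clear();
      grow(nodes, X, y, idx, 0, n, mtry, min_node, recs);
      for (size_t k = 0; k < recs.size(); ++k) {
        const SplitRec& r = recs[k];
        importance(s, r.pred) += r.improve;
        const std::vector<double>& bb = brk[r.pred];
        int b = (int)(std::upper_bound(bb.begin(), bb.end(), r.value) -
                      bb.begin()) - 1;
        if (b < 0) b = 0;
        if (b >= nbins) b = nbins - 1;
        binned[s + (R_xlen_t)S * (r.pred + (R_xlen_t)p * b)] += r.improve;
      }
      for (int i = 0; i < n; ++i) {
        if (!inbag[i]) {
          oob_sum[i] += predict_tree(nodes, X, i);
          oob_cnt[i] += 1;
        }
      }
    }
    // out-of-bag R^2
    double ybar = 0.0;
    int nv = 0;
    for (int i = 0; i < n; ++i) if (oob_cnt[i] > 0) { ybar += y[i]; ++nv; }
    if (nv < 2) { r2[s] = NA_REAL; continue; }
    ybar /= nv;
    double ssr = 0.0, sst = 0.0;
    for (int i = 0; i < n; ++i) {
      if (oob_cnt[i] == 0) continue;
      double pred = oob_sum[i] / oob_cnt[i];
      ssr += (y[i] - pred) * (y[i] - pred);
      sst += (y[i] - ybar) * (y[i] - ybar);
    }
    r2[s] = (sst > 0) ? 1.0 - ssr / sst : NA_REAL;
  }
  binned.attr("dim") = IntegerVector::create(S, p, nbins);
  return List::create(_["r2"] = r2, _["importance"] = importance,
                      _["binned"] = binned);
}
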