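// Classification random forest with per-tree column subsampling and Gini
// node-purity variable importance.
//
// Contracts that the rest of the package relies on:
//  * each tree sees a bootstrap resample of size N (with replacement) and a
//    uniformly random floor(feature_frac * P) subset of columns;
//  * splits maximize the impurity reduction
//      dI = p(A) I(A) - p(AL) I(AL) - p(AR) I(AR),
//    with I the Gini impurity and p(.) = node count / N; equal-gain ties are
//    broken by the tree's random feature order (a fixed global order would
//    systematically funnel importance into early columns, which breaks the
//    exchangeability between true variables and their permutation synthetics
//    that the noise threshold relies on), then by lowest threshold within a
//    column (thresholds are midpoints of consecutive distinct values,
//    scanned ascending);
//  * per-column importance is the sum of dI over all splits on the column
//    across the ensemble, divided by the number of trees;
//  * prediction is a majority vote over trees, ties to the lowest class;
//  * all randomness flows from one integer seed through a self-contained
//    splitmix64 stream, so identical inputs give bit-identical output.
//
// Cohorts here are small (tens of patients) while columns are many (true +
// synthetic scores), so nodes are found by filtering one global presorted
// order per column with a per-row node-id array rather than by maintaining
// partitioned index sets.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

namespace {

struct SplitMix {
  uint64_t s;
  explicit SplitMix(uint64_t seed) : s(seed) { (void)next(); }
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  int unif_int(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

struct NodeTask {
  int id;                  // index into the tree's node arrays
  std::vector<int> counts; // weighted class counts
  int n_rows;              // distinct rows in the node
};

} // namespace

// [[Rcpp::export]]
List rf_fit_cpp(NumericMatrix X, IntegerVector y, int n_classes, int n_trees,
                double feature_frac, bool bootstrap, double seed) {
  const int N = X.nrow(), P = X.ncol();
  if (N < 2) stop("need at least 2 samples");
  {
    int observed = 0;
    std::vector<char> seen(n_classes, 0);
    for (int i = 0; i < N; ++i) {
      if (y[i] < 0 || y[i] >= n_classes) stop("class label out of range");
      if (!seen[y[i]]) { seen[y[i]] = 1; ++observed; }
    }
    if (observed < 2) stop("outcome has a single class");
  }
  int m_feat = std::max(1, (int)std::floor(feature_frac * P + 1e-9));
  if (m_feat > P) m_feat = P;

  // presort every column once (ties by row index for determinism)
  std::vector<int> ord0((size_t)P * N);
  const double* Xd = REAL(X);
  for (int p = 0; p < P; ++p) {
    int* o = ord0.data() + (size_t)p * N;
    for (int i = 0; i < N; ++i) o[i] = i;
    const double* xv = Xd + (size_t)p * N;
    std::stable_sort(o, o + N, [xv](int a, int b) { return xv[a] < xv[b]; });
  }
  const int* yv = INTEGER(y);

  std::vector<double> imp(P, 0.0);
  std::vector<int> tree_root;
  std::vector<int> all_feature, all_left, all_right, all_pred;
  std::vector<double> all_thr;

  SplitMix master((uint64_t)(int64_t)seed);
  std::vector<int> perm(P), feats;
  std::vector<int> w(N), node_of(N);
  std::vector<int> lc(n_classes), best_lc(n_classes);
  std::vector<NodeTask> stack;
  // per-tree node arrays
  std::vector<int> t_feature, t_left, t_right, t_pred;
  std::vector<double> t_thr;

  for (int t = 0; t < n_trees; ++t) {
    SplitMix rng(master.next());

    std::fill(w.begin(), w.end(), bootstrap ? 0 : 1);
    if (bootstrap) for (int i = 0; i < N; ++i) w[rng.unif_int(N)]++;

    // feature subset by partial Fisher-Yates; kept in shuffled order so that
    // equal-gain ties resolve to a uniformly random column, not a fixed one
    for (int p = 0; p < P; ++p) perm[p] = p;
    for (int j = 0; j < m_feat; ++j) std::swap(perm[j], perm[j + rng.unif_int(P - j)]);
    feats.assign(perm.begin(), perm.begin() + m_feat);

    t_feature.clear(); t_thr.clear(); t_left.clear(); t_right.clear(); t_pred.clear();
    auto new_node = [&]() {
      t_feature.push_back(-1); t_thr.push_back(0.0);
      t_left.push_back(-1); t_right.push_back(-1); t_pred.push_back(-1);
      return (int)t_feature.size() - 1;
    };

    NodeTask root;
    root.id = new_node();
    root.counts.assign(n_classes, 0);
    root.n_rows = 0;
    for (int i = 0; i < N; ++i) {
      node_of[i] = w[i] > 0 ? root.id : -1;
      if (w[i] > 0) { root.counts[yv[i]] += w[i]; ++root.n_rows; }
    }
    stack.clear();
    stack.push_back(std::move(root));

    while (!stack.empty()) {
      NodeTask nd = std::move(stack.back());
      stack.pop_back();
      const int nid = nd.id;

      int n_node = 0, n_pos = 0, best_class = 0, best_count = -1;
      double sumsq = 0.0;
      for (int k = 0; k < n_classes; ++k) {
        const int c = nd.counts[k];
        n_node += c;
        if (c > 0) ++n_pos;
        if (c > best_count) { best_count = c; best_class = k; }
        sumsq += (double)c * c;
      }
      if (n_pos <= 1 || nd.n_rows < 2) { t_pred[nid] = best_class; continue; }

      const double s_node = sumsq / n_node;
      double s_best = s_node;
      int best_col = -1;
      double best_thr = 0.0;

      for (int fi = 0; fi < m_feat; ++fi) {
        const int col = feats[fi];
        const double* xv = Xd + (size_t)col * N;
        const int* ord = ord0.data() + (size_t)col * N;
        std::fill(lc.begin(), lc.end(), 0);
        int nl = 0;
        double sl = 0.0, prev = 0.0;
        bool started = false;
        for (int i = 0; i < N; ++i) {
          const int r = ord[i];
          if (node_of[r] != nid) continue;
          const double v = xv[r];
          if (started && v > prev) {
            // candidate boundary: left = rows seen so far
            const int nr = n_node - nl;
            double cross = 0.0;
            for (int k = 0; k < n_classes; ++k)
              cross += (double)nd.counts[k] * lc[k];
            const double s = sl / nl + (sumsq - 2.0 * cross + sl) / nr;
            if (s > s_best) {
              s_best = s; best_col = col; best_thr = 0.5 * (prev + v);
              std::copy(lc.begin(), lc.end(), best_lc.begin());
            }
          }
          const int cw = w[r];
          sl += (double)cw * (2 * lc[yv[r]] + cw);
          lc[yv[r]] += cw;
          nl += cw;
          prev = v;
          started = true;
        }
      }

      if (best_col < 0) { t_pred[nid] = best_class; continue; }

      imp[best_col] += (s_best - s_node) / N;
      t_feature[nid] = best_col;
      t_thr[nid] = best_thr;

      NodeTask left, right;
      left.id = new_node(); right.id = new_node();
      t_left[nid] = left.id; t_right[nid] = right.id;
      left.counts.assign(best_lc.begin(), best_lc.end());
      right.counts.assign(n_classes, 0);
      for (int k = 0; k < n_classes; ++k)
        right.counts[k] = nd.counts[k] - best_lc[k];
      left.n_rows = 0; right.n_rows = 0;
      const double* xv = Xd + (size_t)best_col * N;
      for (int r = 0; r < N; ++r) {
        if (node_of[r] != nid) continue;
        if (xv[r] <= best_thr) { node_of[r] = left.id; ++left.n_rows; }
        else { node_of[r] = right.id; ++right.n_rows; }
      }
      stack.push_back(std::move(right));
      stack.push_back(std::move(left));
    }

    const int off = (int)all_feature.size();
    tree_root.push_back(off);
    for (size_t k = 0; k < t_feature.size(); ++k) {
      all_feature.push_back(t_feature[k]);
      all_thr.push_back(t_thr[k]);
      all_left.push_back(t_left[k] < 0 ? -1 : t_left[k] + off);
      all_right.push_back(t_right[k] < 0 ? -1 : t_right[k] + off);
      all_pred.push_back(t_pred[k]);
    }
  }

  NumericVector importance(P);
  for (int p = 0; p < P; ++p) importance[p] = imp[p] / n_trees;

  return List::create(
    _["importance"] = importance,
    _["n_trees"] = n_trees,
    _["n_classes"] = n_classes,
    _["n_features"] = P,
    _["tree_root"] = IntegerVector(tree_root.begin(), tree_root.end()),
    _["node_feature"] = IntegerVector(all_feature.begin(), all_feature.end()),
    _["node_threshold"] = NumericVector(all_thr.begin(), all_thr.end()),
    _["node_left"] = IntegerVector(all_left.begin(), all_left.end()),
    _["node_right"] = IntegerVector(all_right.begin(), all_right.end()),
    _["node_pred"] = IntegerVector(all_pred.begin(), all_pred.end()));
}

// [[Rcpp::export]]
IntegerVector rf_predict_cpp(List fit, NumericMatrix X) {
  const int n_classes = fit["n_classes"];
  IntegerVector root = fit["tree_root"];
  IntegerVector nf = fit["node_feature"];
  NumericVector nt = fit["node_threshold"];
  IntegerVector nl = fit["node_left"];
  IntegerVector nr = fit["node_right"];
  IntegerVector np = fit["node_pred"];
  const int P = fit["n_features"];
  if (X.ncol() != P) stop("feature count mismatch with training data");
  const int n = X.nrow(), T = root.size();
  IntegerVector out(n);
  std::vector<int> votes(n_classes);
  for (int i = 0; i < n; ++i) {
    std::fill(votes.begin(), votes.end(), 0);
    for (int t = 0; t < T; ++t) {
      int node = root[t];
      while (np[node] < 0) node = (X(i, nf[node]) <= nt[node]) ? nl[node] : nr[node];
      ++votes[np[node]];
    }
    int best = 0;
    for (int k = 1; k < n_classes; ++k) if (votes[k] > votes[best]) best = k;
    out[i] = best;
  }
  return out;
}
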