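// Multivariate regression trees with a Mahalanobis split cost.
//
// The cost of a leaf L is sum_i (y_i - ybar_L)' Lambda (y_i - ybar_L).
// With W the Cholesky factor of Lambda (W'W = Lambda) and z = W y, this is
// the plain multivariate sum of squared deviations of the whitened outcomes,
// so the learner works throughout on pre-whitened Z and evaluates candidate
// splits with prefix sums:  cost(rows) = sum ||z||^2 - ||sum z||^2 / n.
// Leaf payloads are componentwise means of the *raw* outcomes Y.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double GAIN_TOL_REL = 1e-12;
// Candidates must beat the incumbent by this (relative) margin: exact cost
// ties -- e.g. two features inducing the same row partition -- then resolve
// to the lowest feature index / lowest threshold regardless of the order in
// which prefix sums accumulate rounding error.
static const double TIE_TOL_REL = 1e-9;

struct SplitChoice {
  bool found = false;
  int feature = -1;      // 0-based
  double threshold = 0.0;
  double cost_children = 0.0;
};

static double node_cost(const arma::mat& Z, const arma::uvec& rows) {
  const arma::mat Zs = Z.rows(rows);
  const arma::rowvec s = arma::sum(Zs, 0);
  return arma::accu(arma::square(Zs)) - arma::dot(s, s) / Zs.n_rows;
}

// Exhaustive scan over the given candidate features; thresholds are midpoints
// of consecutive distinct sorted values. Ties in total child cost are broken
// by lowest feature index then lowest threshold (features must arrive sorted
// ascending; positions are scanned in ascending threshold order).
static SplitChoice best_split_node(const arma::mat& X, const arma::mat& Z,
                                   const arma::uvec& rows,
                                   const arma::uvec& features,
                                   const int min_leaf,
                                   const double parent_cost) {
  SplitChoice best;
  const arma::uword n = rows.n_elem;
  if (n < 2 * static_cast<arma::uword>(min_leaf)) return best;
  const arma::uword k = Z.n_cols;
  double best_cost = R_PosInf;
  const double tie_eps = TIE_TOL_REL * std::max(1.0, parent_cost);

  arma::vec xv(n);
  arma::mat Zs(n, k);
  for (arma::uword fi = 0; fi < features.n_elem; ++fi) {
    const arma::uword f = features(fi);
    for (arma::uword i = 0; i < n; ++i) xv(i) = X(rows(i), f);
    const arma::uvec ord = arma::sort_index(xv, "ascend");
    for (arma::uword i = 0; i < n; ++i) Zs.row(i) = Z.row(rows(ord(i)));

    // prefix sums over the sorted order
    arma::rowvec S(k, arma::fill::zeros);
    double q = 0.0;
    const arma::rowvec Stot = arma::sum(Zs, 0);
    const double qtot = arma::accu(arma::square(Zs));
    for (arma::uword i = 1; i < n; ++i) {
      S += Zs.row(i - 1);
      q += arma::dot(Zs.row(i - 1), Zs.row(i - 1));
      if (i < static_cast<arma::uword>(min_leaf) ||
          n - i < static_cast<arma::uword>(min_leaf)) continue;
      const double lo = xv(ord(i - 1)), hi = xv(ord(i));
      if (!(lo < hi)) continue;  // only between distinct values
      const double cost_l = q - arma::dot(S, S) / i;
      const arma::rowvec Sr = Stot - S;
      const double cost_r = (qtot - q) - arma::dot(Sr, Sr) / (n - i);
      const double tot = cost_l + cost_r;
      if (tot < best_cost - tie_eps) {
        best_cost = tot;
        best.feature = static_cast<int>(f);
        best.threshold = lo + (hi - lo) / 2.0;
        best.cost_children = tot;
        best.found = true;
      }
    }
  }
  if (best.found) {
    const double tol = GAIN_TOL_REL * std::max(1.0, parent_cost);
    if (!(parent_cost - best.cost_children > tol)) best.found = false;
  }
  return best;
}

// [[Rcpp::export(name = ".best_split_cpp")]]
List best_split_cpp(const arma::mat& X, const arma::mat& Z, int min_leaf) {
  arma::uvec rows = arma::regspace<arma::uvec>(0, X.n_rows - 1);
  arma::uvec feats = arma::regspace<arma::uvec>(0, X.n_cols - 1);
  const double pc = node_cost(Z, rows);
  SplitChoice s = best_split_node(X, Z, rows, feats, min_leaf, pc);
  return List::create(
      _["found"] = s.found,
      _["feature"] = s.found ? s.feature + 1 : NA_INTEGER,
      _["threshold"] = s.found ? s.threshold : NA_REAL,
      _["cost_parent"] = pc,
      _["cost_children"] = s.found ? s.cost_children : NA_REAL);
}

struct NodeRec {
  int feature = -1;  // -1: leaf
  double threshold = 0.0;
  int left = -1, right = -1;
  int n = 0;
  int depth = 0;
};

// Grow one tree on the (already bootstrapped) row set `idx`.
// Accumulates per-feature impurity decreases into `mdi` (length p),
// normalised by the tree's training-sample count.
static List fit_tree(const arma::mat& X, const arma::mat& Y, const arma::mat& Z,
                     const arma::uvec& idx, int max_depth, int min_leaf,
                     int mtry, std::mt19937& rng, arma::vec& mdi) {
  const int p = static_cast<int>(X.n_cols);
  const arma::uword k = Y.n_cols;
  const double n_tree = static_cast<double>(idx.n_elem);

  std::vector<NodeRec> nodes;
  std::vector<arma::uvec> node_rows;
  nodes.emplace_back();
  nodes[0].n = static_cast<int>(idx.n_elem);
  node_rows.push_back(idx);

  std::vector<int> open{0};
  arma::uvec all_feats = arma::regspace<arma::uvec>(0, p - 1);

  while (!open.empty()) {
    const int ni = open.back();
    open.pop_back();
    const arma::uvec rows = node_rows[ni];
    NodeRec& nd = nodes[ni];
    if (nd.depth >= max_depth ||
        rows.n_elem < 2 * static_cast<arma::uword>(min_leaf)) {
      continue;  // stays a leaf
    }
    arma::uvec feats;
    if (mtry >= p) {
      feats = all_feats;
    } else {
      // partial Fisher-Yates draw of `mtry` distinct features, then sorted
      std::vector<int> pool(p);
      for (int j = 0; j < p; ++j) pool[j] = j;
      for (int j = 0; j < mtry; ++j) {
        std::uniform_int_distribution<int> u(j, p - 1);
        std::swap(pool[j], pool[u(rng)]);
      }
      std::vector<int> pick(pool.begin(), pool.begin() + mtry);
      std::sort(pick.begin(), pick.end());
      feats = arma::conv_to<arma::uvec>::from(pick);
    }
    const double pc = node_cost(Z, rows);
    const SplitChoice s = best_split_node(X, Z, rows, feats, min_leaf, pc);
    if (!s.found) continue;

    std::vector<arma::uword> lv, rv;
    lv.reserve(rows.n_elem);
    rv.reserve(rows.n_elem);
    for (arma::uword i = 0; i < rows.n_elem; ++i) {
      if (X(rows(i), s.feature) <= s.threshold) lv.push_back(rows(i));
      else rv.push_back(rows(i));
    }
    const int li = static_cast<int>(nodes.size());
    const int ri = li + 1;
    // write through index, not `nd`: emplace_back may reallocate `nodes`
    nodes[ni].feature = s.feature;
    nodes[ni].threshold = s.threshold;
    nodes[ni].left = li;
    nodes[ni].right = ri;
    const int d = nodes[ni].depth;
    mdi(s.feature) += (pc - s.cost_children) / n_tree;

    nodes.emplace_back();
    nodes.back().n = static_cast<int>(lv.size());
    nodes.back().depth = d + 1;
    node_rows.push_back(arma::uvec(lv));
    nodes.emplace_back();
    nodes.back().n = static_cast<int>(rv.size());
    nodes.back().depth = d + 1;
    node_rows.push_back(arma::uvec(rv));
    open.push_back(li);
    open.push_back(ri);
  }

  const int nn = static_cast<int>(nodes.size());
  IntegerVector feature(nn), left(nn), right(nn), nvec(nn);
  NumericVector threshold(nn);
  arma::mat leaf_mean(nn, k, arma::fill::zeros);
  for (int i = 0; i < nn; ++i) {
    feature[i] = nodes[i].feature;
    threshold[i] = nodes[i].threshold;
    left[i] = nodes[i].left;
    right[i] = nodes[i].right;
    nvec[i] = nodes[i].n;
    if (nodes[i].feature < 0) {
      leaf_mean.row(i) = arma::mean(Y.rows(node_rows[i]), 0);
    }
  }
  return List::create(
      _["feature"] = feature, _["threshold"] = threshold, _["left"] = left,
      _["right"] = right, _["n"] = nvec, _["leaf_mean"] = leaf_mean);
}

// [[Rcpp::export(name = ".fit_forest_cpp")]]
List fit_forest_cpp(const arma::mat& X, const arma::mat& Y, const arma::mat& Z,
                    const arma::umat& boot, int max_depth, int min_leaf,
                    int mtry, const IntegerVector& tree_seeds) {
  const int T = boot.n_cols;
  const int p = static_cast<int>(X.n_cols);
  List trees(T);
  arma::mat mdi(p, T, arma::fill::zeros);
  for (int t = 0; t < T; ++t) {
    std::mt19937 rng(static_cast<unsigned int>(tree_seeds[t]));
    arma::vec m = mdi.col(t);
    arma::uvec idx = boot.col(t);  // 0-based row indices
    trees[t] = fit_tree(X, Y, Z, idx, max_depth, min_leaf, mtry, rng, m);
    mdi.col(t) = m;
  }
  return List::create(_["trees"] = trees, _["mdi"] = mdi);
}

static arma::rowvec tree_predict_row(const List& tree, const arma::rowvec& x) {
  const IntegerVector feature = tree["feature"];
  const NumericVector threshold = tree["threshold"];
  const IntegerVector left = tree["left"];
  const IntegerVector right = tree["right"];
  const arma::mat leaf_mean = tree["leaf_mean"];
  int i = 0;
  while (feature[i] >= 0) {
    i = (x(feature[i]) <= threshold[i]) ? left[i] : right[i];
  }
  return leaf_mean.row(i);
}

// Mean and across-tree (population, divide-by-T) standard deviation of the
// per-tree leaf predictions at each row of X.
// [[Rcpp::export(name = ".predict_forest_cpp")]]
List predict_forest_cpp(const List& trees, const arma::mat& X, int k) {
  const int T = trees.size();
  const arma::uword n = X.n_rows;
  arma::mat s1(n, k, arma::fill::zeros), s2(n, k, arma::fill::zeros);
  for (int t = 0; t < T; ++t) {
    const List tree = trees[t];
    for (arma::uword i = 0; i < n; ++i) {
      const arma::rowvec h = tree_predict_row(tree, X.row(i));
      s1.row(i) += h;
      s2.row(i) += arma::square(h);
    }
  }
  const arma::mat mean = s1 / T;
  arma::mat varm = s2 / T - arma::square(mean);
  // clamp cancellation noise so identical per-tree predictions report sd 0
  for (arma::uword i = 0; i < varm.n_elem; ++i) {
    const double m = mean(i);
    if (varm(i) < 1e-12 * std::max(1.0, m * m)) varm(i) = 0.0;
  }
  return List::create(_["mean"] = mean, _["sd"] = arma::sqrt(varm));
}
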