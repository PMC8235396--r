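#include <Rcpp.h>
using namespace Rcpp;

// A flattened regression tree: nodes 0..K-1 with
//   var[k]   : 0-based predictor index at an internal node, -1 at a leaf
//   split[k] : split value; x <= split goes left
//   left[k], right[k] : 0-based child node ids
//   pred[k]  : leaf prediction (leaves only)
// This mirrors the structure ranger stores per tree.

struct FlatTree {
  IntegerVector left, right, var;
  NumericVector split, pred;
};

static FlatTree unpack(const List& tree) {
  FlatTree t;
  t.left = tree["left"];
  t.right = tree["right"];
  t.var = tree["var"];
  t.split = tree["split"];
  t.pred = tree["pred"];
  return t;
}

// Predict one sample, optionally overriding one predictor's value
// (override_var < 0 means no override).
static inline double predict_one(const FlatTree& t, const NumericMatrix& X,
                                 int row, int override_var,
                                 double override_val) {
  int node = 0;
  while (t.var[node] >= 0) {
    int v = t.var[node];
    double x = (v == override_var) ? override_val : X(row, v);
    node = (x <= t.split[node]) ? t.left[node] : t.right[node];
  }
  return t.pred[node];
}

// [[Rcpp::export]]
NumericMatrix predict_trees_cpp(List trees, NumericMatrix X) {
  const int n = X.nrow(), B = trees.size();
  NumericMatrix out(n, B);
  for (int b = 0; b < B; ++b) {
    FlatTree t = unpack(trees[b]);
    for (int i = 0; i < n; ++i) out(i, b) = predict_one(t, X, i, -1, 0.0);
  }
  return out;
}

// Per-tree OOB permutation importance (increase in OOB MSE after permuting
// one predictor among that tree's OOB samples).
//
// oob_idx:  list of B integer vectors (1-based row indices OOB in tree b)
// perms:    list of B integer matrices, n_oob_b x p; column j permutes the
//           OOB positions for predictor j (1-based)
// Returns a p x B matrix of imp_jb; trees with < 2 OOB samples yield NA.
// [[Rcpp::export]]
NumericMatrix perm_importance_cpp(List trees, NumericMatrix X, NumericVector y,
                                  List oob_idx, List perms) {
  const int p = X.ncol(), B = trees.size();
  NumericMatrix imp(p, B);
  std::fill(imp.begin(), imp.end(), NA_REAL);
  for (int b = 0; b < B; ++b) {
    IntegerVector oob = oob_idx[b];
    const int m = oob.size();
    if (m < 2) continue;
    FlatTree t = unpack(trees[b]);
    // baseline OOB MSE of tree b
    double mse0 = 0.0;
    for (int k = 0; k < m; ++k) {
      int row = oob[k] - 1;
      double e = y[row] - predict_one(t, X, row, -1, 0.0);
      mse0 += e * e;
    }
    mse0 /= m;
    IntegerMatrix perm = perms[b];
    for (int j = 0; j < p; ++j) {
      double mse1 = 0.0;
      for (int k = 0; k < m; ++k) {
        int row = oob[k] - 1;
        int donor = oob[perm(k, j) - 1] - 1; // permuted-within-OOB value of Xj
        double e = y[row] - predict_one(t, X, row, j, X(donor, j));
        mse1 += e * e;
      }
      imp(j, b) = mse1 / m - mse0;
    }
  }
  return imp;
}
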