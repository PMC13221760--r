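// Exact TreeSHAP (path-dependent) in double precision for a forest of
// regression trees. Split semantics follow the gradient-boosting backend:
// a row goes to the "yes" child when float(x) < float(threshold), to the
// "missing" child when x is NA. Node weights ("cover") supply the
// conditional-expectation fractions.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

struct PathElement {
  int feature_index;
  double zero_fraction;
  double one_fraction;
  double pweight;
};

static void extend_path(std::vector<PathElement> &path, int unique_depth,
                        double zero_fraction, double one_fraction,
                        int feature_index) {
  path[unique_depth].feature_index = feature_index;
  path[unique_depth].zero_fraction = zero_fraction;
  path[unique_depth].one_fraction = one_fraction;
  path[unique_depth].pweight = (unique_depth == 0 ? 1.0 : 0.0);
  for (int i = unique_depth - 1; i >= 0; --i) {
    path[i + 1].pweight += one_fraction * path[i].pweight * (i + 1.0) /
      (unique_depth + 1.0);
    path[i].pweight = zero_fraction * path[i].pweight *
      (unique_depth - i) / (unique_depth + 1.0);
  }
}

static void unwind_path(std::vector<PathElement> &path, int unique_depth,
                        int path_index) {
  const double one_fraction = path[path_index].one_fraction;
  const double zero_fraction = path[path_index].zero_fraction;
  double next_one_portion = path[unique_depth].pweight;
  for (int i = unique_depth - 1; i >= 0; --i) {
    if (one_fraction != 0) {
      const double tmp = path[i].pweight;
      path[i].pweight = next_one_portion * (unique_depth + 1.0) /
        ((i + 1.0) * one_fraction);
      next_one_portion = tmp - path[i].pweight * zero_fraction *
        (unique_depth - i) / (unique_depth + 1.0);
    } else {
      path[i].pweight = (path[i].pweight * (unique_depth + 1.0)) /
        (zero_fraction * (unique_depth - i));
    }
  }
  for (int i = path_index; i < unique_depth; ++i) {
    path[i].feature_index = path[i + 1].feature_index;
    path[i].zero_fraction = path[i + 1].zero_fraction;
    path[i].one_fraction = path[i + 1].one_fraction;
  }
}

static double unwound_path_sum(const std::vector<PathElement> &path,
                               int unique_depth, int path_index) {
  const double one_fraction = path[path_index].one_fraction;
  const double zero_fraction = path[path_index].zero_fraction;
  double next_one_portion = path[unique_depth].pweight;
  double total = 0.0;
  for (int i = unique_depth - 1; i >= 0; --i) {
    if (one_fraction != 0) {
      const double tmp = next_one_portion * (unique_depth + 1.0) /
        ((i + 1.0) * one_fraction);
      total += tmp;
      next_one_portion = path[i].pweight - tmp * zero_fraction *
        ((unique_depth - i) / (unique_depth + 1.0));
    } else {
      total += (path[i].pweight / zero_fraction) /
        ((unique_depth - i) / (unique_depth + 1.0));
    }
  }
  return total;
}

struct Tree {
  const int *feature;   // -1 at leaves
  const double *threshold;
  const int *yes;
  const int *no;
  const int *missing;
  const double *cover;
  const double *value;  // leaf values
};

static void tree_shap_recursive(const Tree &tree, const double *x,
                                double *phi, int node,
                                std::vector<PathElement> path,  // by value
                                int unique_depth,
                                double parent_zero_fraction,
                                double parent_one_fraction,
                                int parent_feature_index) {
  if ((int)path.size() < unique_depth + 1) path.resize(unique_depth + 1);
  extend_path(path, unique_depth, parent_zero_fraction, parent_one_fraction,
              parent_feature_index);

  if (tree.feature[node] < 0) {  // leaf
    for (int i = 1; i <= unique_depth; ++i) {
      const double w = unwound_path_sum(path, unique_depth, i);
      const PathElement &el = path[i];
      phi[el.feature_index] += w * (el.one_fraction - el.zero_fraction) *
        tree.value[node];
    }
    return;
  }

  const int split_feature = tree.feature[node];
  const double xval = x[split_feature];
  int hot, cold;
  if (ISNAN(xval)) {
    hot = tree.missing[node];
    cold = (hot == tree.yes[node]) ? tree.no[node] : tree.yes[node];
  } else if ((float)xval < (float)tree.threshold[node]) {
    hot = tree.yes[node];
    cold = tree.no[node];
  } else {
    hot = tree.no[node];
    cold = tree.yes[node];
  }
  const double hot_zero_fraction = tree.cover[hot] / tree.cover[node];
  const double cold_zero_fraction = tree.cover[cold] / tree.cover[node];
  double incoming_zero_fraction = 1.0;
  double incoming_one_fraction = 1.0;

  int path_index = 0;
  for (; path_index <= unique_depth; ++path_index)
    if (path[path_index].feature_index == split_feature) break;
  if (path_index != unique_depth + 1) {
    incoming_zero_fraction = path[path_index].zero_fraction;
    incoming_one_fraction = path[path_index].one_fraction;
    unwind_path(path, unique_depth, path_index);
    unique_depth -= 1;
  }

  path.resize(unique_depth + 2);
  tree_shap_recursive(tree, x, phi, hot, path, unique_depth + 1,
                      hot_zero_fraction * incoming_zero_fraction,
                      incoming_one_fraction, split_feature);
  tree_shap_recursive(tree, x, phi, cold, path, unique_depth + 1,
                      cold_zero_fraction * incoming_zero_fraction,
                      0.0, split_feature);
}

// [[Rcpp::export(name = ".treeshap_cpp")]]
NumericMatrix treeshap_cpp(NumericMatrix X, IntegerVector treeOffset,
                           IntegerVector feature, NumericVector threshold,
                           IntegerVector yes, IntegerVector no,
                           IntegerVector missing, NumericVector cover,
                           NumericVector value) {
  const int n = X.nrow();
  const int m = X.ncol();
  const int ntree = treeOffset.size() - 1;
  NumericMatrix phi(n, m + 1);  // last column: bias (expected value)

  // per-tree expected value (cover-weighted leaf mean) goes to the bias
  std::vector<double> tree_expect(ntree, 0.0);
  for (int t = 0; t < ntree; ++t) {
    const int off = treeOffset[t];
    const int nn = treeOffset[t + 1] - off;
    double s = 0.0;
    for (int j = 0; j < nn; ++j)
      if (feature[off + j] < 0) s += cover[off + j] * value[off + j];
    tree_expect[t] = s / cover[off];  // root holds total cover
  }

  std::vector<double> xrow(m);
  std::vector<double> phirow(m + 1);
  for (int r = 0; r < n; ++r) {
    for (int j = 0; j < m; ++j) xrow[j] = X(r, j);
    std::fill(phirow.begin(), phirow.end(), 0.0);
    for (int t = 0; t < ntree; ++t) {
      const int off = treeOffset[t];
      Tree tree;
      tree.feature = &feature[off];
      tree.threshold = &threshold[off];
      tree.yes = &yes[off];
      tree.no = &no[off];
      tree.missing = &missing[off];
      tree.cover = &cover[off];
      tree.value = &value[off];
      std::vector<PathElement> path(2);
      tree_shap_recursive(tree, xrow.data(), phirow.data(), 0, path, 0,
                          1.0, 1.0, -1);
      phirow[m] += tree_expect[t];
    }
    for (int j = 0; j <= m; ++j) phi(r, j) = phirow[j];
  }
  return phi;
}
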