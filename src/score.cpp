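#include <Rcpp.h>
using namespace Rcpp;

// Fitch pass over bitmask-encoded unordered characters.
// po: postorder edge matrix (parent, child), 1-based node ids.
// masks: nnode x nchar; tip rows hold non-zero state bitmasks, internal
// rows 0 (= not yet assigned). Returns per-character step counts.
// [[Rcpp::export]]
IntegerVector fitch_masks_cpp(IntegerMatrix po, IntegerMatrix masks) {
  const int nch = masks.ncol(), ne = po.nrow();
  IntegerVector steps(nch);
  IntegerMatrix mk = clone(masks);
  for (int e = 0; e < ne; e++) {
    const int p = po(e, 0) - 1, c = po(e, 1) - 1;
    for (int j = 0; j < nch; j++) {
      const int a = mk(p, j), b = mk(c, j);
      if (a == 0) {
        mk(p, j) = b;
      } else {
        const int inter = a & b;
        if (inter == 0) {
          steps[j]++;
          mk(p, j) = a | b;
        } else {
          mk(p, j) = inter;
        }
      }
    }
  }
  return steps;
}

// Generalized (Sankoff) parsimony total under a step-cost matrix.
// dp0: nnode x ns; tip rows 0 for allowed states / Inf otherwise,
// internal rows 0. Returns the minimum over root states.
// [[Rcpp::export]]
double sankoff_total_cpp(IntegerMatrix po, NumericMatrix cost,
                         NumericMatrix dp0) {
  const int ns = cost.nrow(), ne = po.nrow();
  NumericMatrix dp = clone(dp0);
  for (int e = 0; e < ne; e++) {
    const int p = po(e, 0) - 1, c = po(e, 1) - 1;
    for (int s = 0; s < ns; s++) {
      double best = R_PosInf;
      for (int t = 0; t < ns; t++) {
        const double w = dp(c, t) + cost(t, s);
        if (w < best) best = w;
      }
      dp(p, s) += best;
    }
  }
  const int root = po(ne - 1, 0) - 1;
  double out = R_PosInf;
  for (int s = 0; s < ns; s++) {
    if (dp(root, s) < out) out = dp(root, s);
  }
  return out;
}
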