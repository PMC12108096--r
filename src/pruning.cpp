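#include "pruning.h"
using namespace Rcpp;

// Root partial log-likelihoods for every pattern x category.
// Returns list with P x k matrices root_log0 / root_log1 (log partial
// likelihood at the root for OFF / ON, before the root prior).
// [[Rcpp::export(name = ".prune_root_partials")]]
List prune_root_partials(IntegerMatrix patterns, IntegerVector child,
                         IntegerVector parent, NumericVector elen, int nTip,
                         NumericVector rates, double pi, NumericVector cats) {
  PruneTree tr = make_tree(child, parent, elen, nTip);
  const int P = patterns.nrow(), k = cats.size();
  NumericMatrix r0(P, k), r1(P, k);
  std::vector<double> L0(tr.nNode), L1(tr.nNode);
  std::vector<int> pat(nTip);
  std::vector<double> rt(rates.begin(), rates.end());
  std::vector<TransP> EP;
  for (int c = 0; c < k; ++c) {
    edge_probs(tr, rt.data(), pi, cats[c], EP);
    for (int p = 0; p < P; ++p) {
      for (int i = 0; i < nTip; ++i) pat[i] = patterns(p, i);
      double l0, l1;
      prune_pattern(tr, pat.data(), EP, L0, L1, l0, l1);
      r0(p, c) = l0; r1(p, c) = l1;
    }
  }
  return List::create(_["root_log0"] = r0, _["root_log1"] = r1);
}

// Total log-likelihood over compressed patterns (counts-weighted).
// [[Rcpp::export(name = ".prune_total_loglik")]]
double prune_total_loglik(IntegerMatrix patterns, NumericVector counts,
                          IntegerVector child, IntegerVector parent,
                          NumericVector elen, int nTip, NumericVector rates,
                          double pi, NumericVector cats) {
  PruneTree tr = make_tree(child, parent, elen, nTip);
  std::vector<double> L0(tr.nNode), L1(tr.nNode), cc(cats.begin(), cats.end());
  std::vector<double> rt(rates.begin(), rates.end());
  return organ_loglik(tr, patterns, counts, rt.data(), pi, cc, L0, L1);
}

// Discretized-gamma category rates (equal-mass conditional means, mean 1).
// [[Rcpp::export(name = ".gamma_cats_cpp")]]
NumericVector gamma_cats_cpp(double xi, int k) {
  std::vector<double> a;
  gamma_cats(xi, k, a);
  return NumericVector(a.begin(), a.end());
}
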