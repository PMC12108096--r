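#pragma once
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

// Two-state CTMC with stationary ON frequency pi, normalized so the mean
// flow at stationarity is 1: Q01 = 1/(2(1-pi)) (OFF->ON), Q10 = 1/(2 pi).
// With total scale s over time t, e = exp(-s t / (2 pi (1-pi))) and
// P(OFF->ON) = pi (1-e), P(ON->OFF) = (1-pi)(1-e).
struct TransP { double p00, p01, p10, p11; };

inline TransP trans_prob2(double pi, double s, double t) {
  double e = std::exp(-s * t / (2.0 * pi * (1.0 - pi)));
  TransP P;
  P.p01 = pi * (1.0 - e);
  P.p00 = 1.0 - P.p01;
  P.p10 = (1.0 - pi) * (1.0 - e);
  P.p11 = 1.0 - P.p10;
  return P;
}

// Rooted binary tree as postorder edge lists (children before parents),
// 0-based node ids: tips 0..nTip-1, root = nTip.
struct PruneTree {
  int nTip, nNode, root;
  std::vector<int> child, parent;
  std::vector<double> elen;
};

inline PruneTree make_tree(const Rcpp::IntegerVector& child,
                           const Rcpp::IntegerVector& parent,
                           const Rcpp::NumericVector& elen, int nTip) {
  PruneTree tr;
  tr.nTip = nTip;
  tr.nNode = 2 * nTip - 1;
  tr.root = nTip;  // ape convention: root id nTip+1, passed 0-based
  int E = child.size();
  tr.child.resize(E); tr.parent.resize(E); tr.elen.resize(E);
  for (int e = 0; e < E; ++e) {
    tr.child[e] = child[e] - 1;
    tr.parent[e] = parent[e] - 1;
    tr.elen[e] = elen[e];
  }
  return tr;
}

// Per-edge transition probabilities at one category scale (shared by all
// patterns, so the exponentials are computed once per likelihood call).
inline void edge_probs(const PruneTree& tr, const double* rates, double pi,
                       double a, std::vector<TransP>& P) {
  const int E = (int) tr.child.size();
  P.resize(E);
  for (int e = 0; e < E; ++e) P[e] = trans_prob2(pi, rates[e] * a, tr.elen[e]);
}

// Root partial log-likelihoods (per state) for one tip pattern given
// precomputed edge probabilities. pat: 0 = OFF, 1 = ON, -1 = missing.
inline void prune_pattern(const PruneTree& tr, const int* pat,
                          const std::vector<TransP>& P,
                          std::vector<double>& L0, std::vector<double>& L1,
                          double& out_l0, double& out_l1) {
  const int nn = tr.nNode;
  double logscale = 0.0;
  for (int i = 0; i < nn; ++i) { L0[i] = 1.0; L1[i] = 1.0; }
  for (int i = 0; i < tr.nTip; ++i) {
    if (pat[i] == 0) L1[i] = 0.0;
    else if (pat[i] == 1) L0[i] = 0.0;
  }
  const int E = (int) tr.child.size();
  for (int e = 0; e < E; ++e) {
    const int ch = tr.child[e], pa = tr.parent[e];
    const double m0 = P[e].p00 * L0[ch] + P[e].p01 * L1[ch];
    const double m1 = P[e].p10 * L0[ch] + P[e].p11 * L1[ch];
    L0[pa] *= m0; L1[pa] *= m1;
    double mx = std::max(L0[pa], L1[pa]);
    if (mx > 0.0 && mx < 1e-200) {
      L0[pa] /= mx; L1[pa] /= mx; logscale += std::log(mx);
    }
  }
  out_l0 = (L0[tr.root] > 0.0) ? std::log(L0[tr.root]) + logscale : R_NegInf;
  out_l1 = (L1[tr.root] > 0.0) ? std::log(L1[tr.root]) + logscale : R_NegInf;
}

// Discretized gamma with mean 1: k equal-mass intervals of
// Gamma(shape = xi, rate = xi); category rate = conditional mean, via the
// mean-value identity E[X ; X<=q] = P(Gamma(xi+1, xi) <= q) when mean = 1.
inline void gamma_cats(double xi, int k, std::vector<double>& a) {
  a.resize(k);
  if (k == 1) { a[0] = 1.0; return; }
  double prevF = 0.0;
  for (int c = 0; c < k; ++c) {
    double F;
    if (c == k - 1) F = 1.0;
    else {
      double q = R::qgamma((c + 1.0) / k, xi, 1.0 / xi, 1, 0);
      F = R::pgamma(q, xi + 1.0, 1.0 / xi, 1, 0);
    }
    a[c] = k * (F - prevF);
    prevF = F;
  }
}

// Total log-likelihood of one organ over compressed patterns: per pattern,
// log (1/k) sum_c [(1-pi) L0c + pi L1c], summed with pattern counts.
inline double organ_loglik(const PruneTree& tr, const Rcpp::IntegerMatrix& pat,
                           const Rcpp::NumericVector& counts,
                           const double* rates, double pi,
                           const std::vector<double>& cats,
                           std::vector<double>& L0, std::vector<double>& L1) {
  const int P = pat.nrow();
  const int k = (int) cats.size();
  const double wlog = -std::log((double) k);
  std::vector<double> lr0(P * k), lr1(P * k);
  std::vector<TransP> EP;
  std::vector<int> patbuf(tr.nTip);
  for (int c = 0; c < k; ++c) {
    edge_probs(tr, rates, pi, cats[c], EP);
    for (int p = 0; p < P; ++p) {
      for (int i = 0; i < tr.nTip; ++i) patbuf[i] = pat(p, i);
      prune_pattern(tr, patbuf.data(), EP, L0, L1, lr0[p * k + c], lr1[p * k + c]);
    }
  }
  double total = 0.0;
  for (int p = 0; p < P; ++p) {
    double best = R_NegInf;
    std::vector<double> lc(k);
    for (int c = 0; c < k; ++c) {
      const double l0 = lr0[p * k + c], l1 = lr1[p * k + c];
      double m = std::max(l0, l1);
      lc[c] = (m == R_NegInf) ? R_NegInf
        : m + std::log((1.0 - pi) * std::exp(l0 - m) + pi * std::exp(l1 - m));
      if (lc[c] > best) best = lc[c];
    }
    double s = 0.0;
    for (int c = 0; c < k; ++c) s += std::exp(lc[c] - best);
    total += counts[p] * (best + std::log(s) + wlog);
  }
  return total;
}
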