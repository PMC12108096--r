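#include "pruning.h"
using namespace Rcpp;

// Exact event-time CTMC simulation of binary states down the tree.
// Edges must be in postorder; they are traversed in reverse (parents before
// children). Root states are supplied (one per gene). Records the realized
// number of transitions per gene per edge.
// [[Rcpp::export(name = ".simulate_tips_cpp")]]
List simulate_tips_cpp(IntegerVector child, IntegerVector parent,
                       NumericVector elen, int nTip, NumericVector rates,
                       double pi, NumericVector gene_scale,
                       IntegerVector root_state) {
  const int E = child.size();
  const int nGene = gene_scale.size();
  const int nNode = 2 * nTip - 1;
  IntegerMatrix tips(nGene, nTip);
  IntegerMatrix ntrans(nGene, E);
  std::vector<int> node_state(nNode);
  const double q01 = 1.0 / (2.0 * (1.0 - pi));  // OFF -> ON
  const double q10 = 1.0 / (2.0 * pi);          // ON -> OFF
  for (int g = 0; g < nGene; ++g) {
    node_state[nTip] = root_state[g];  // root id = nTip (0-based)
    for (int e = E - 1; e >= 0; --e) {
      int s = node_state[parent[e] - 1];
      const double scale = rates[e] * gene_scale[g];
      int k = 0;
      if (scale > 0.0) {
        double t = 0.0;
        const double len = elen[e];
        while (true) {
          const double out = scale * (s == 0 ? q01 : q10);
          t += R::exp_rand() / out;
          if (t > len) break;
          s ^= 1;
          ++k;
        }
      }
      node_state[child[e] - 1] = s;
      ntrans(g, e) = k;
    }
    for (int i = 0; i < nTip; ++i) tips(g, i) = node_state[i];
  }
  return List::create(_["tips"] = tips, _["transitions"] = ntrans);
}
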