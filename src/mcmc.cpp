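#include "pruning.h"
using namespace Rcpp;

// State vector layout (doubles):
// 0 pi1, 1 pi2, 2 xi1, 3 xi2, 4 phi, 5 alpha1, 6 alpha2, 7 theta,
// 8 beta1, 9 beta2, 10 c, 11..(10+E) logr organ1, (11+E)..(10+2E) logr organ2.
static const int IDX_LOGR = 11;

static double state_log_prior(const std::vector<double>& st, int E, int varmode) {
  const double pi1 = st[0], pi2 = st[1], xi1 = st[2], xi2 = st[3];
  const double phi = st[4], a1 = st[5], a2 = st[6], th = st[7];
  const double b1 = st[8], b2 = st[9], c = st[10];
  if (pi1 <= 0 || pi1 >= 1 || pi2 <= 0 || pi2 >= 1) return R_NegInf;
  if (xi1 <= 0 || xi2 <= 0) return R_NegInf;
  if (phi < -10 || phi > 1) return R_NegInf;
  if (a1 <= 0 || a1 >= 1 || a2 <= 0 || a2 >= 1) return R_NegInf;
  if (th < 1e-4 || th > 5) return R_NegInf;
  if (b1 <= 0 || b1 >= 1 || b2 <= 0 || b2 >= 1) return R_NegInf;
  if (c <= -1 || c >= 1) return R_NegInf;
  double lp = 0.0;
  // pi_i ~ Beta(1,1): contributes 0
  lp += R::dlnorm(xi1, std::log(5.0), 0.587, 1);
  lp += R::dlnorm(xi2, std::log(5.0), 0.587, 1);
  lp += -std::log(11.0);                       // phi ~ Uniform(-10, 1)
  lp += R::dbeta(a1, 2.0, 2.0, 1) + R::dbeta(a2, 2.0, 2.0, 1);
  lp += -std::log(th) - std::log(std::log(5.0 / 1e-4));  // theta ~ LogUniform
  lp += R::dbeta(b1, 10.0, 10.0, 1) + R::dbeta(b2, 10.0, 10.0, 1);
  lp += std::log(0.5);                         // LKJ(eta=1), 2x2: density 1/2
  const double mu1 = phi + std::log(2.0 * a1);
  const double mu2 = phi + std::log(2.0 * a2);
  const double s1sq = (varmode == 0) ? th + 2.0 * b1 : th * 2.0 * b1;
  const double s2sq = (varmode == 0) ? th + 2.0 * b2 : th * 2.0 * b2;
  const double cov = c * std::sqrt(s1sq * s2sq);
  const double det = s1sq * s2sq - cov * cov;
  if (det <= 0) return R_NegInf;
  const double ldet = std::log(det);
  for (int b = 0; b < E; ++b) {
    const double x = st[IDX_LOGR + b] - mu1;
    const double y = st[IDX_LOGR + E + b] - mu2;
    const double q = (s2sq * x * x - 2.0 * cov * x * y + s1sq * y * y) / det;
    lp += -M_LN_SQRT_2PI * 2.0 - 0.5 * ldet - 0.5 * q;
  }
  return lp;
}

static double reflect(double x, double lo, double hi) {
  const double range = hi - lo;
  for (int i = 0; i < 100 && (x < lo || x > hi); ++i) {
    if (x < lo) x = 2.0 * lo - x;
    if (x > hi) x = 2.0 * hi - x;
  }
  if (x < lo || x > hi) x = lo + R::runif(0.0, 1.0) * range;
  return x;
}

struct LikCtx {
  PruneTree tr;
  IntegerMatrix pat1, pat2;
  NumericVector cnt1, cnt2;
  std::vector<double> L0, L1;
  double lik(int organ, const std::vector<double>& st,
             const std::vector<double>& cats1, const std::vector<double>& cats2) {
    const int E = (int) tr.child.size();
    const double* rates;
    std::vector<double> r(E);
    if (organ == 1) {
      for (int b = 0; b < E; ++b) r[b] = std::exp(st[IDX_LOGR + b]);
      rates = r.data();
      return organ_loglik(tr, pat1, cnt1, rates, st[0], cats1, L0, L1);
    } else {
      for (int b = 0; b < E; ++b) r[b] = std::exp(st[IDX_LOGR + E + b]);
      rates = r.data();
      return organ_loglik(tr, pat2, cnt2, rates, st[1], cats2, L0, L1);
    }
  }
};

// Metropolis-Hastings sampler over the full model state. Move cycle per
// generation: reflected sliding windows on bounded scalars, multipliers on
// positive scalars, per-branch Gaussian log-rate moves per organ, a joint
// (phi, all log r) shift, and a correlation walk. Proposal scales are tuned
// toward 0.23-0.44 acceptance during burn-in only.
// [[Rcpp::export(name = ".mcmc_run_cpp")]]
List mcmc_run_cpp(IntegerMatrix pat1, NumericVector cnt1, IntegerMatrix pat2,
                  NumericVector cnt2, IntegerVector child, IntegerVector parent,
                  NumericVector elen, int nTip, NumericVector init, int k,
                  int generations, int burnin, int thin, int varmode,
                  int tune_interval, NumericVector init_scales) {
  LikCtx ctx;
  ctx.tr = make_tree(child, parent, elen, nTip);
  ctx.pat1 = pat1; ctx.pat2 = pat2; ctx.cnt1 = cnt1; ctx.cnt2 = cnt2;
  ctx.L0.resize(ctx.tr.nNode); ctx.L1.resize(ctx.tr.nNode);
  const int E = child.size();
  const int npar = 11 + 2 * E;
  std::vector<double> st(init.begin(), init.end());

  const int NMOVE = 14;
  std::vector<double> scales(init_scales.begin(), init_scales.end());
  std::vector<long> acc(NMOVE, 0), att(NMOVE, 0), acc_tune(NMOVE, 0), att_tune(NMOVE, 0);

  std::vector<double> cats1, cats2;
  gamma_cats(st[2], k, cats1);
  gamma_cats(st[3], k, cats2);

  double pri = state_log_prior(st, E, varmode);
  double lik1 = ctx.lik(1, st, cats1, cats2);
  double lik2 = ctx.lik(2, st, cats1, cats2);
  if (!R_finite(pri) || !R_finite(lik1) || !R_finite(lik2))
    stop("non-finite initial posterior");

  const int nsamp = (generations > burnin) ? (generations - burnin) / thin : 0;
  NumericMatrix trace(nsamp, npar + 2);
  int row = 0;

  // scalar move table: {state index, move type, kind, lo, hi, organ affected}
  // kind 0 = slide-reflect, 1 = multiplier; organ 0 = prior-only
  const int m_sidx[11]  = {0, 1, 2, 3, 4, 5, 6, 7, 8, 9, 10};
  const int m_type[11]  = {0, 1, 2, 3, 4, 5, 6, 7, 8, 9, 10};
  const int m_kind[11]  = {0, 0, 1, 1, 0, 0, 0, 1, 0, 0, 0};
  const double m_lo[11] = {0, 0, 0, 0, -10, 0, 0, 0, 0, 0, -1};
  const double m_hi[11] = {1, 1, 0, 0, 1, 1, 1, 0, 1, 1, 1};
  const int m_org[11]   = {1, 2, 1, 2, 0, 0, 0, 0, 0, 0, 0};

  for (int gen = 1; gen <= generations; ++gen) {
    // --- scalar moves ---
    for (int m = 0; m < 11; ++m) {
      const int si = m_sidx[m], mt = m_type[m];
      const double old = st[si];
      double lhr = 0.0, prop;
      if (m_kind[m] == 0) {
        prop = reflect(old + R::runif(-scales[mt], scales[mt]), m_lo[m], m_hi[m]);
      } else {
        const double f = std::exp(scales[mt] * (R::runif(0.0, 1.0) - 0.5));
        prop = old * f;
        lhr = std::log(f);
      }
      st[si] = prop;
      std::vector<double> ncats1 = cats1, ncats2 = cats2;
      if (si == 2) gamma_cats(prop, k, ncats1);
      if (si == 3) gamma_cats(prop, k, ncats2);
      const double npri = state_log_prior(st, E, varmode);
      double nlik1 = lik1, nlik2 = lik2;
      if (R_finite(npri)) {
        if (m_org[m] == 1) nlik1 = ctx.lik(1, st, ncats1, ncats2);
        if (m_org[m] == 2) nlik2 = ctx.lik(2, st, ncats1, ncats2);
      }
      ++att[mt]; ++att_tune[mt];
      const double la = (npri + nlik1 + nlik2) - (pri + lik1 + lik2) + lhr;
      if (R_finite(npri) && std::log(R::runif(0.0, 1.0)) < la) {
        pri = npri; lik1 = nlik1; lik2 = nlik2;
        cats1 = ncats1; cats2 = ncats2;
        ++acc[mt]; ++acc_tune[mt];
      } else {
        st[si] = old;
      }
    }
    // --- per-branch log-rate moves ---
    for (int organ = 1; organ <= 2; ++organ) {
      const int mt = 10 + organ;  // 11 or 12
      const int off = IDX_LOGR + (organ - 1) * E;
      for (int b = 0; b < E; ++b) {
        const double old = st[off + b];
        st[off + b] = old + R::norm_rand() * scales[mt];
        const double npri = state_log_prior(st, E, varmode);
        const double nlik = ctx.lik(organ, st, cats1, cats2);
        const double olik = (organ == 1) ? lik1 : lik2;
        ++att[mt]; ++att_tune[mt];
        if (std::log(R::runif(0.0, 1.0)) < (npri + nlik) - (pri + olik)) {
          pri = npri;
          if (organ == 1) lik1 = nlik; else lik2 = nlik;
          ++acc[mt]; ++acc_tune[mt];
        } else {
          st[off + b] = old;
        }
      }
    }
    // --- joint (phi, all log r) shift ---
    {
      const int mt = 13;
      const double delta = R::norm_rand() * scales[mt];
      ++att[mt]; ++att_tune[mt];
      const double nphi = st[4] + delta;
      if (nphi >= -10 && nphi <= 1) {
        std::vector<double> old(st);
        st[4] = nphi;
        for (int j = 0; j < 2 * E; ++j) st[IDX_LOGR + j] += delta;
        const double npri = state_log_prior(st, E, varmode);
        const double nlik1 = ctx.lik(1, st, cats1, cats2);
        const double nlik2 = ctx.lik(2, st, cats1, cats2);
        if (std::log(R::runif(0.0, 1.0)) <
            (npri + nlik1 + nlik2) - (pri + lik1 + lik2)) {
          pri = npri; lik1 = nlik1; lik2 = nlik2;
          ++acc[mt]; ++acc_tune[mt];
        } else {
          st = old;
        }
      }
    }
    // --- burn-in proposal tuning ---
    if (gen <= burnin && tune_interval > 0 && gen % tune_interval == 0) {
      for (int mt = 0; mt < NMOVE; ++mt) {
        if (att_tune[mt] == 0) continue;
        const double r = (double) acc_tune[mt] / (double) att_tune[mt];
        if (r > 0.44) scales[mt] *= 1.25;
        else if (r < 0.23) scales[mt] *= 0.8;
        scales[mt] = std::min(std::max(scales[mt], 1e-4), 50.0);
        acc_tune[mt] = 0; att_tune[mt] = 0;
      }
    }
    if (gen == burnin) {  // report post-burn-in acceptance only
      std::fill(acc.begin(), acc.end(), 0L);
      std::fill(att.begin(), att.end(), 0L);
    }
    // --- record ---
    if (gen > burnin && (gen - burnin) % thin == 0 && row < nsamp) {
      for (int j = 0; j < 11; ++j) trace(row, j) = st[j];
      for (int j = 0; j < 2 * E; ++j)
        trace(row, 11 + j) = std::exp(st[IDX_LOGR + j]);
      trace(row, npar) = pri + lik1 + lik2;
      trace(row, npar + 1) = lik1 + lik2;
      ++row;
    }
    if (gen % 512 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector acc_rate(NMOVE), sc(NMOVE);
  for (int mt = 0; mt < NMOVE; ++mt) {
    acc_rate[mt] = att[mt] > 0 ? (double) acc[mt] / (double) att[mt] : NA_REAL;
    sc[mt] = scales[mt];
  }
  return List::create(_["trace"] = trace, _["acceptance"] = acc_rate,
                      _["scales"] = sc);
}

// Full log posterior of a state vector (used for from-scratch recomputation
// checks against the incrementally tracked value).
// [[Rcpp::export(name = ".state_log_posterior_cpp")]]
NumericVector state_log_posterior_cpp(NumericVector state, IntegerMatrix pat1,
                                      NumericVector cnt1, IntegerMatrix pat2,
                                      NumericVector cnt2, IntegerVector child,
                                      IntegerVector parent, NumericVector elen,
                                      int nTip, int k, int varmode) {
  LikCtx ctx;
  ctx.tr = make_tree(child, parent, elen, nTip);
  ctx.pat1 = pat1; ctx.pat2 = pat2; ctx.cnt1 = cnt1; ctx.cnt2 = cnt2;
  ctx.L0.resize(ctx.tr.nNode); ctx.L1.resize(ctx.tr.nNode);
  const int E = child.size();
  std::vector<double> st(state.begin(), state.end());
  std::vector<double> cats1, cats2;
  gamma_cats(st[2], k, cats1);
  gamma_cats(st[3], k, cats2);
  const double pri = state_log_prior(st, E, varmode);
  const double l1 = ctx.lik(1, st, cats1, cats2);
  const double l2 = ctx.lik(2, st, cats1, cats2);
  return NumericVector::create(_["log_prior"] = pri, _["log_lik"] = l1 + l2,
                               _["log_posterior"] = pri + l1 + l2);
}
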