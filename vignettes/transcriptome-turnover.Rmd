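---
title: "Modeling evolutionary turnover of organ transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling evolutionary turnover of organ transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyturnover)
```

## The problem

Orthologous genes gain and lose active expression in particular organs over
evolutionary time — *transcriptome turnover*. Given replicated RNA-seq from
the same organ in several species, a Bayesian mixture classifier (such as the
published *zigzag* model) can assign each gene, in each species and organ, a
posterior probability of being actively expressed. `phyturnover` takes those
probabilities plus a fixed time-calibrated species tree and answers: how fast
do genes switch ON/OFF in each organ, how do rates vary among genes and among
branches, how correlated are the two organs' rate histories, and which genes
were expressed in the common ancestor?

## The model

**States and discretization.** Each gene × species × organ cell is classified
as ON if its probability of expression `p` exceeds `1 - alpha`, OFF if `p <
alpha`, and missing otherwise; the inequalities are strict, so boundary
values become missing. `alpha` trades information for confidence; 0.1 is the
default, and 0.05–0.25 behave similarly in practice. Cells whose
leave-one-library-out probability re-estimates span a range greater than 0.25
are also set to missing: such genes violate the classifier's assumption of a
shared latent state across replicates.

**Relative rate matrix.** Expression states evolve as a two-state
continuous-time Markov chain at stationarity. With stationary ON frequency
$\pi_i$ in organ $i$, the activation and deactivation rates are
$Q_{01} = 1/(2(1-\pi_i))$ and $Q_{10} = 1/(2\pi_i)$, which normalizes the
mean transition rate at stationarity to one:
$\pi_i Q_{10} + (1-\pi_i) Q_{01} = 1$. Actual rates are products
$r_{i,b}\, a_{i,g}\, Q_i$: a branch rate times a gene-rate scale times the
normalized matrix, so branch rates are in units of expected state changes
per gene per million years.

**Among-gene rate variation.** Gene scales $a_{i,g}$ follow a discretized
gamma distribution with mean fixed to 1 (shape = rate = $\xi_i$), cut into
$k = 6$ equal-mass intervals, each represented by its conditional mean; the
mixture weights are all $1/6$ and categories are marginalized analytically in
the likelihood (no latent category augmentation). $\xi_i$ is a precision:
small values mean a few genes carry most of the turnover.

**Among-branch rate variation.** Per branch $b$, the log rates of the two
organs are jointly bivariate normal, $\log r_b \sim \mathrm{MVN}(\mu,
\Sigma)$: an uncorrelated (iid across branches) relaxed clock with a
cross-organ correlation. Means are $\mu_i = \phi + \ln(2\alpha_i)$ with a
shared scale $\phi \sim \mathrm{Uniform}(-10, 1)$ (natural log of rate per
MY) and organ shares $\alpha_i \sim \mathrm{Beta}(2, 2)$; variances are
$\sigma_i^2 = \theta + 2\beta_i$ with $\theta \sim \mathrm{LogUniform}(10^{-4},
5)$ and $\beta_i \sim \mathrm{Beta}(10, 10)$; the $2\times 2$ correlation
matrix has an LKJ($\eta = 1$) prior, i.e. the correlation $c$ is uniform on
$(-1, 1)$. Remaining priors: $\pi_i \sim \mathrm{Beta}(1,1)$, $\xi_i \sim
\mathrm{LogNormal}(\ln 5, 0.587)$.

Two definitions of $\sigma_i^2$ are supported. The default, *additive*
($\theta + 2\beta_i$), follows the model summary verbatim; it implies a
floor of roughly 0.6 on $\sigma_i^2$ because $2\beta_i$ concentrates around
1. A *multiplicative* option ($\theta \cdot 2\beta_i$) is exposed in
`run_config(variance_mode=)` because it is the natural analogue of the mean
construction ($\mu_i = \phi + \ln 2\alpha_i$ is multiplicative on the rate
scale) and does not impose that floor. We deliberately expose both rather
than guessing; all tests run under the additive default. A practical
consequence of the additive floor: when the true among-branch spread is
smaller than the prior floor, the posterior of the correlation $c$ tends to
be pushed upward, while $\pi_i$ and time-weighted mean rates remain well
calibrated (the parameter-recovery tests check exactly those).

The $(\phi, \alpha_1, \alpha_2)$ parameterization is redundant — the
likelihood depends on them only through $\mu_i$ — and is kept as specified;
$\mu_i$ itself is identifiable, and an invariance test asserts that
compensating changes to $\phi$ and $\alpha_i$ leave the likelihood
unchanged.

**Likelihood.** Felsenstein pruning over the fixed chronogram with
closed-form two-state transition probabilities
($P(\mathrm{OFF}\to\mathrm{ON}) = \pi(1 - e^{-s t / (2\pi(1-\pi))})$ at
total scale $s$); missing tips contribute the partial likelihood $(1, 1)$;
the root prior is the stationary distribution $(1-\pi_i, \pi_i)$. Genes
with identical tip-state patterns are compressed to unique patterns with
counts, which makes likelihood cost nearly independent of gene count for
slowly evolving data.

## Sampling and diagnostics

The posterior is explored by Metropolis–Hastings with a fixed per-generation
move cycle: reflected sliding windows on the bounded scalars ($\pi_i$,
$\alpha_i$, $\beta_i$, $\phi$, $c$), multipliers on the positive scalars
($\xi_i$, $\theta$), a Gaussian move on each branch's log rate in each
organ, and a joint shift of $\phi$ and all log rates (which moves the
overall rate level without changing the prior residuals). Proposal scales
are tuned toward 0.23–0.44 acceptance during burn-in only and frozen
afterwards, preserving detailed balance for retained samples. Defaults
follow the study setup: 10,000 generations, sampling every 5, 10% burn-in,
convergence judged by PSRF < 1.2 across independent chains and ESS ≥ 200.
All randomness flows through R's seeded RNG (including inside the C++
sampler), so a seed plus a config reproduces a trace bitwise.

Initialization draws from the prior until the posterior is finite (at most
100 attempts). The tracked log posterior is re-derivable from any trace row
with `total_log_posterior()`; a test recomputes it from scratch along the
trace and requires agreement to 1e-8.

## The synthetic-data generator

`simulate_states()` draws root states from the stationary prior and runs
exact event-time CTMC simulation down every branch, recording realized
transition counts (used by closed-form oracle checks: at stationarity the
expected number of events on a branch is rate × length). Branch rates are
drawn from the bivariate lognormal calibrated so the time-weighted mean rate
matches a target; gene scales are drawn from the equal-weight gamma
categories. Two artifact scenarios mirror the robustness analyses:
`fast_subset_scenario()` (constant rates, equal activation/deactivation,
with exactly ⌈5%⌉ of genes 100-fold faster) and `apply_misclassification()`
(exactly ⌈1%⌉ of each species × organ's non-missing cells flipped; the count
is deterministic so the effect size is reproducible, only placement is
random). `make_probability_fixture()` emulates classifier output:
Beta(200, 1)-shaped probabilities concentrated toward the true state, a
configurable miscalibration fraction drawn uniform on (0, 1), and optional
per-library jitter for the sensitivity filter.

What the generator does *not* emulate: read-level noise, genome annotation
quality differences among species, cross-tissue contamination, or gene-level
correlation between organs. Passing tests therefore show the inference
machinery is correct under the model's own assumptions, not that those
assumptions hold for any particular RNA-seq dataset.

The study conditions used throughout testing: the bundled synthetic 11-taxon
ultrametric tree with root age 25 MY (the published chronogram's node ages
are not available, so the fixture's ages are invented, with two 1 MY
terminal branches to probe tip-branch sensitivity), 2,000 genes, stationary
frequencies (0.7, 0.6), time-weighted mean rates (0.002, 0.0016) changes per
gene per MY, $\xi = 5$, correlation 0.5.

## Downstream statistics

- **Gene rates and concentration.** Per retained sample, a gene's category
  posterior is proportional to $L_c/k$; its rate is the posterior-weighted
  category mean, and expected turnover events are rate × $\sum_b r_b \ell_b$
  (exact at stationarity by the unit-mean-flow normalization; an
  approximation far from stationarity). The cumulative turnover curve ranks
  genes fastest-first and accumulates normalized event mass; equal rates
  give the diagonal.
- **PDMR.** Percent difference of mean rate between a focal and a reference
  gene group, computed per posterior sample; its mean (M-PDMR) is compared
  against a null of 1,000 random equal-size partitions, summarized by an
  upper-tail rank probability.
- **Ancestral states.** Marginal root posteriors per gene, and joint
  root-OFF/tip-ON probabilities (expression gains on a focal lineage)
  computed by tip clamping and renormalization against the unclamped
  marginal; a coherence identity (clamped states partition the root-OFF
  mass) is tested to 1e-10 against enumeration.
- **Leave-k-out cross-validation.** A random 5% of observed cells are
  masked, the model refit, and each withheld state predicted by tip
  clamping. Accuracy is reported both as mean probability assigned to the
  withheld call and as argmax agreement (the two diverge when predictions
  are not extreme), overall and per species.

## Numerical choices

Ultrametricity is checked to a relative 1e-6 and violations warn rather than
abort (real chronograms carry rounding). Discretization ties go to missing.
Transition probabilities use the closed form, verified to 1e-12 against a
truncated matrix-exponential series; pruning is verified to 1e-10 against
exhaustive enumeration over internal-node states. Gamma category means use
the regularized incomplete gamma of shape $\xi + 1$, so the weighted mean is
exactly 1 up to quadrature error (< 1e-8). The sampler walks log branch
rates, so the MVN prior needs no Jacobian. HPD intervals use the
shortest-interval rule. ESS uses the initial-positive-sequence truncation; a
constant series is defined as ESS 0 with a warning. Leave-one-library-out
masking uses a strict `> 0.25` range rule (a range of exactly 0.25 is kept).

Problem sizes in the test suite are chosen to exercise the study conditions
at desk scale: recovery experiments use 2,000 genes and 5,000-generation
chains (20 replicates), artifact scenarios 2,000 genes and 2,000-generation
chains (10 replicates each), prior-recovery 50,000 generations with
Kolmogorov–Smirnov checks on near-independent subsamples, and the end-to-end
pipeline 1,000 genes. The acceptance script runs the full default 10,000
generations with two chains.

## Known limitations

The model assumes genes evolve independently; regulatory interactions
violate this in ways whose effect is unknown. Gene-level cross-organ state
changes are not modeled — only branch-level rate correlation. The tree and
root age are treated as known. Tip-state uncertainty is discretized away
rather than integrated over; genes with uncertain states become missing
data. The additive/multiplicative ambiguity in the branch-rate variance
definition is exposed as configuration rather than resolved.

## A short example

```{r example, eval = FALSE}
tree <- example_tree()
sim <- simulate_states(tree, 500, pi = c(0.7, 0.6),
                       mean_rate = c(0.002, 0.0016), seed = 1)
fx <- make_probability_fixture(sim$states, seed = 2)
states <- lapply(fx, function(x) discretize_probabilities(x$probs, alpha = 0.1))
fit <- run_mcmc(states, tree, run_config(generations = 5000, seed = 3))
tidy(fit)
branch_rate_summary(fit)$organ_mean
ancestral_root_marginal(fit)$summary
```
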