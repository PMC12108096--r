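#' Simulate binary expression evolution on a tree
#'
#' Forward-simulates ON/OFF states for `n_genes` in two organs by exact
#' event-time CTMC sampling along each branch: the root state is drawn from
#' the stationary prior `(1 - pi, pi)`, and each branch evolves with total
#' rate `r_b * a_g` times the normalized rate matrix, recording every
#' realized transition. Branch rates are either supplied explicitly or drawn
#' from a bivariate lognormal whose median is calibrated so the time-weighted
#' mean rate is near `mean_rate`; gene scales are either supplied or drawn
#' from the discretized-gamma categories with equal weights.
#'
#' @param tree A `timetree`.
#' @param n_genes Number of genes (>= 1).
#' @param pi Length-2 stationary ON frequencies.
#' @param mean_rate Length-2 target mean branch rates (changes/gene/MY).
#' @param rate_sdlog Length-2 log-sd of branch rates (0 = constant rates).
#' @param correlation Between-organ branch-rate correlation.
#' @param xi Length-2 gamma precisions for among-gene variation.
#' @param k Number of gamma categories.
#' @param branch_rates Optional E x 2 matrix of branch rates (overrides the
#'   lognormal draw).
#' @param gene_scales Optional n_genes x 2 matrix of gene rate scales
#'   (overrides the gamma draw).
#' @param organs Organ names.
#' @param seed Optional integer seed.
#' @return A `sim_result`: list with `states` (named list of wide state
#'   tibbles), `branch_rates` (E x 2), `gene_scales` (n x 2),
#'   `gene_categories` (n x 2), `root_states` (n x 2), `transitions` (list of
#'   n x E integer matrices), `tree`, `seed`.
#' @export
simulate_states <- function(tree, n_genes, pi = c(0.5, 0.5),
                            mean_rate = c(0.002, 0.002),
                            rate_sdlog = c(0.3, 0.3), correlation = 0.5,
                            xi = c(5, 5), k = 6, branch_rates = NULL,
                            gene_scales = NULL,
                            organs = c("organ1", "organ2"), seed = NULL) {
  stopifnot(inherits(tree, "timetree"), n_genes >= 1)
  if (!is.null(seed)) set.seed(seed)
  ta <- tree_arrays(tree)
  E <- length(ta$elen)
  if (is.null(branch_rates)) {
    mu <- log(mean_rate)
    Sig <- diag(rate_sdlog) %*% matrix(c(1, correlation, correlation, 1), 2) %*%
      diag(rate_sdlog)
    z <- matrix(rnorm(2 * E), E, 2)
    if (any(rate_sdlog > 0)) z <- z %*% chol(Sig) else z[] <- 0
    branch_rates <- exp(sweep(z, 2, mu - rate_sdlog^2 / 2, "+"))
  }
  branch_rates <- as.matrix(branch_rates)
  stopifnot(nrow(branch_rates) == E, ncol(branch_rates) == 2)
  gene_categories <- NULL
  if (is.null(gene_scales)) {
    gene_scales <- matrix(1, n_genes, 2)
    gene_categories <- matrix(1L, n_genes, 2)
    for (i in 1:2) {
      cats <- gamma_categories(xi[i], k = k)
      idx <- sample.int(k, n_genes, replace = TRUE)
      gene_categories[, i] <- idx
      gene_scales[, i] <- cats$rates[idx]
    }
  }
  gene_scales <- as.matrix(gene_scales)
  states <- list()
  transitions <- list()
  root_states <- matrix(0L, n_genes, 2)
  genes <- sprintf("g%05d", seq_len(n_genes))
  for (i in 1:2) {
    roots <- rbinom(n_genes, 1, pi[i])
    sim <- .simulate_tips_cpp(ta$child, ta$parent, ta$elen, ta$n_tip,
                              branch_rates[, i], pi[i], gene_scales[, i],
                              roots)
    tips <- sim$tips
    colnames(tips) <- tree$phylo$tip.label
    st <- as_tibble(as.data.frame(tips))
    st <- tibble(gene = genes, !!!st)
    states[[organs[i]]] <- st
    transitions[[organs[i]]] <- sim$transitions
    root_states[, i] <- roots
  }
  colnames(root_states) <- organs
  colnames(branch_rates) <- organs
  structure(list(states = states, branch_rates = branch_rates,
                 gene_scales = gene_scales, gene_categories = gene_categories,
                 root_states = root_states, transitions = transitions,
                 tree = tree, seed = seed),
            class = "sim_result")
}

#' Constant-rate simulation with a fast gene subset
#'
#' Artifact scenario: every gene evolves at the same constant branch rate
#' with activation rate equal to deactivation rate (`pi = 0.5`), except a
#' fixed fraction of genes (exactly `ceiling(fast_fraction * n_genes)`,
#' chosen uniformly at random) whose rate is multiplied by `multiplier`.
#'
#' @param tree A `timetree`.
#' @param n_genes Number of genes.
#' @param rate Constant branch rate (changes/gene/MY).
#' @param fast_fraction Fraction of fast genes in \[0, 1\] (default 0.05).
#' @param multiplier Rate multiplier for fast genes (default 100).
#' @param organs Organ names.
#' @param seed Optional integer seed.
#' @return A `sim_result` with an extra `fast_genes` integer index vector.
#' @export
fast_subset_scenario <- function(tree, n_genes, rate = 0.002,
                                 fast_fraction = 0.05, multiplier = 100,
                                 organs = c("organ1", "organ2"), seed = NULL) {
  if (fast_fraction < 0 || fast_fraction > 1) abort("fast_fraction must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  n_fast <- min(ceiling(fast_fraction * n_genes), n_genes)
  fast <- if (n_fast > 0) sort(sample.int(n_genes, n_fast)) else integer(0)
  scales <- matrix(1, n_genes, 2)
  scales[fast, ] <- multiplier
  E <- nrow(branches(tree))
  sim <- simulate_states(tree, n_genes, pi = c(0.5, 0.5),
                         branch_rates = matrix(rate, E, 2),
                         gene_scales = scales, organs = organs, seed = NULL)
  sim$fast_genes <- fast
  sim
}

#' Flip expression states to emulate misclassification
#'
#' For each species and organ, flips a uniformly random subset of
#' `ceiling(fraction * n_genes)` non-missing cells ON <-> OFF; missing cells
#' are untouched. The flip count is deterministic (only placement is random)
#' so the effect size is reproducible at small n.
#'
#' @param states Named list of wide state tibbles (or one tibble).
#' @param fraction Fraction of genes flipped per species and organ.
#' @param seed Optional integer seed.
#' @return Object of the same shape with flipped states.
#' @export
apply_misclassification <- function(states, fraction = 0.01, seed = NULL) {
  if (fraction < 0 || fraction > 1) abort("fraction must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  single <- is.data.frame(states)
  if (single) states <- list(states)
  for (i in seq_along(states)) {
    st <- states[[i]]
    n <- nrow(st)
    for (sp in setdiff(names(st), "gene")) {
      ok <- which(!is.na(st[[sp]]))
      m <- min(ceiling(fraction * n), length(ok))
      if (m > 0) {
        flip <- if (m == length(ok)) ok else sample(ok, m)
        st[[sp]][flip] <- 1L - st[[sp]][flip]
      }
    }
    states[[i]] <- st
  }
  if (single) states[[1]] else states
}

#' Emulate classifier probability tables from true states
#'
#' Builds probability-of-expression fixtures concentrated near the true
#' states: ON cells draw `p ~ Beta(concentration, 1)` (mass near 1), OFF
#' cells `p ~ Beta(1, concentration)` (mass near 0), and with probability
#' `miscalibration_rate` a cell instead draws `p ~ Uniform(0, 1)`. Missing
#' cells stay NA. If `n_libraries` is given, per-library re-estimates are
#' also produced by drawing each library's probability from a Beta centred
#' on the cell value, for exercising [library_sensitivity_filter()].
#'
#' @param states Named list of wide state tibbles (or one tibble).
#' @param concentration Beta concentration (> 1); larger is more decisive.
#' @param miscalibration_rate Fraction of cells with uninformative p.
#' @param n_libraries Optional number of per-library re-estimates.
#' @param library_concentration Concentration of library-level jitter.
#' @param seed Optional integer seed.
#' @return Named list per organ: `probs` (wide tibble) and, when requested,
#'   `per_library` (long tibble `gene`, `species`, `library`, `p`). A single
#'   input tibble returns a single such list.
#' @export
make_probability_fixture <- function(states, concentration = 200,
                                     miscalibration_rate = 0,
                                     n_libraries = NULL,
                                     library_concentration = 100,
                                     seed = NULL) {
  if (concentration <= 1) abort("concentration must be > 1")
  if (!is.null(seed)) set.seed(seed)
  single <- is.data.frame(states)
  if (single) states <- list(states)
  out <- list()
  for (nm in seq_along(states)) {
    st <- states[[nm]]
    probs <- tibble(gene = st$gene)
    for (sp in setdiff(names(st), "gene")) {
      s <- st[[sp]]
      p <- rep(NA_real_, length(s))
      on <- which(!is.na(s) & s == 1L)
      off <- which(!is.na(s) & s == 0L)
      p[on] <- rbeta(length(on), concentration, 1)
      p[off] <- rbeta(length(off), 1, concentration)
      obs <- which(!is.na(s))
      bad <- obs[runif(length(obs)) < miscalibration_rate]
      p[bad] <- runif(length(bad))
      probs[[sp]] <- p
    }
    res <- list(probs = probs)
    if (!is.null(n_libraries)) {
      long <- list()
      for (sp in setdiff(names(st), "gene")) {
        p <- probs[[sp]]
        ok <- which(!is.na(p))
        for (l in seq_len(n_libraries)) {
          pl <- rep(NA_real_, length(p))
          pl[ok] <- rbeta(length(ok), 1 + library_concentration * p[ok],
                          1 + library_concentration * (1 - p[ok]))
          long[[paste(sp, l)]] <- tibble(gene = probs$gene, species = sp,
                                         library = l, p = pl)
        }
      }
      res$per_library <- bind_rows(long)
    }
    out[[nm]] <- res
  }
  names(out) <- names(states)
  if (single) out[[1]] else out
}
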