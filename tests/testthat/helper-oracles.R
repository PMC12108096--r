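# Independent oracles and small fixtures used across the suite.

# Transition probabilities by truncated matrix-exponential series:
# P(t) = sum_n (Q s t)^n / n!, evaluated to high order.
series_transition <- function(pi, scale, t, nterm = 30) {
  Q <- relative_rate_matrix(pi) * scale * t
  # scaling and squaring keeps the truncated series accurate for large Qt
  m <- max(0, ceiling(log2(max(abs(Q)) + 1)))
  Qs <- Q / 2^m
  P <- diag(2)
  term <- diag(2)
  for (n in seq_len(nterm)) {
    term <- term %*% Qs / n
    P <- P + term
  }
  for (i in seq_len(m)) P <- P %*% P
  P
}

# Brute-force likelihood by exhaustive enumeration over the states of all
# internal nodes (and missing tips), summing root states against the
# stationary prior, averaged over rate categories with equal weights.
# root_fix restricts the sum to one root state (for ancestral oracles).
brute_lik <- function(tree, tips, pi, rates, cats = 1, root_fix = NA) {
  phy <- tree$phylo
  ntip <- tree$n_tips
  nn <- 2 * ntip - 1
  edges <- phy$edge
  el <- phy$edge.length
  tipv <- as.integer(tips[phy$tip.label])
  total <- 0
  for (a in cats) {
    Plist <- lapply(seq_len(nrow(edges)), function(e) {
      transition_probability(pi, rates[e] * a, el[e])
    })
    free <- c(which(is.na(tipv)), (ntip + 1):nn)
    lik <- 0
    grid <- expand.grid(rep(list(0:1), length(free)))
    for (gi in seq_len(nrow(grid))) {
      s <- integer(nn)
      s[seq_len(ntip)] <- ifelse(is.na(tipv), 0L, tipv)
      s[free] <- as.integer(grid[gi, ])
      if (!is.na(root_fix) && s[ntip + 1] != root_fix) next
      p <- if (s[ntip + 1] == 1) pi else 1 - pi
      for (e in seq_len(nrow(edges))) {
        p <- p * Plist[[e]][s[edges[e, 1]] + 1, s[edges[e, 2]] + 1]
      }
      lik <- lik + p
    }
    total <- total + lik / length(cats)
  }
  total
}

# all-missing state table over the tips of a tree
missing_states <- function(tree, n_genes) {
  st <- tibble::tibble(gene = sprintf("g%03d", seq_len(n_genes)))
  for (sp in tree$phylo$tip.label) st[[sp]] <- NA_integer_
  st
}

# state tibble from a genes x tips matrix
states_from_matrix <- function(m, tree) {
  colnames(m) <- tree$phylo$tip.label
  tibble::tibble(gene = sprintf("g%03d", seq_len(nrow(m))),
                 !!!as.data.frame(m))
}

# a turnover_fit with a hand-specified single-sample trace, for exercising
# the post-hoc machinery at known parameter values
manual_fit <- function(tree, data, pi, xi = c(5, 5), rates_by_organ,
                       phi = -6, alpha = c(0.5, 0.5), theta = 0.001,
                       beta = c(0.5, 0.5), corr = 0, k = 6) {
  organs <- names(data)
  E <- nrow(branches(tree))
  cp <- lapply(data, phyturnover:::compress_patterns, tree = tree)
  tr <- tibble::as_tibble(as.list(stats::setNames(
    c(pi, xi, phi, alpha, theta, beta, corr,
      rates_by_organ[[1]], rates_by_organ[[2]], 0, 0),
    c(paste0("pi_", organs), paste0("xi_", organs), "phi",
      paste0("alpha_", organs), "theta", paste0("beta_", organs), "corr",
      paste0("r_", organs[1], "_", seq_len(E)),
      paste0("r_", organs[2], "_", seq_len(E)),
      "log_posterior", "log_lik"))))
  tr$.chain <- 1L
  structure(list(trace = tr, acceptance = tibble::tibble(),
                 organs = organs, tree = tree, data = data, patterns = cp,
                 config = run_config(k = k), n_samples = 1L, burnin = 0L),
            class = "turnover_fit")
}

# small shared fit used by several post-hoc tests (built once per run)
fixture_env <- new.env()
small_fit <- function() {
  if (is.null(fixture_env$fit)) {
    tr <- example_tree()
    sim <- simulate_states(tr, 300, pi = c(0.7, 0.6),
                           mean_rate = c(0.002, 0.0016), seed = 71)
    fixture_env$sim <- sim
    fixture_env$fit <- run_mcmc(sim$states, tr,
                                run_config(generations = 800, thin = 5, seed = 72))
  }
  fixture_env
}

# hand-built gene_rates object with prescribed per-draw rate matrices
manual_gene_rates <- function(draws_by_organ, flow = NULL) {
  organs <- names(draws_by_organ)
  genes <- rownames(draws_by_organ[[1]])
  if (is.null(genes)) genes <- sprintf("g%03d", seq_len(nrow(draws_by_organ[[1]])))
  S <- ncol(draws_by_organ[[1]])
  if (is.null(flow)) flow <- lapply(draws_by_organ, function(m) rep(1, S))
  summ <- dplyr::bind_rows(lapply(organs, function(o) {
    m <- draws_by_organ[[o]]
    tibble::tibble(organ = o, gene = genes, mean_rate = rowMeans(m),
                   expected_events = as.numeric(m %*% flow[[o]]) / S)
  }))
  structure(list(summary = summ, draws = draws_by_organ, branch_flow = flow,
                 organs = organs, genes = genes, draw_index = seq_len(S)),
            class = "gene_rates")
}
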