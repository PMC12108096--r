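#' Full parameter state of the evolutionary model
#'
#' One complete assignment of the two-organ model parameters: stationary ON
#' frequencies `pi`, gamma precisions `xi`, the shared log-mean scale `phi`
#' with per-organ proportionality `alpha` (so the log-mean branch rate of
#' organ i is `mu_i = phi + log(2 alpha_i)`), the variance scale `theta` with
#' per-organ proportions `beta`, the between-organ correlation, and the
#' per-branch log rates (one column per organ, rows in postorder branch
#' order).
#'
#' @param pi Length-2 vector of stationary ON frequencies.
#' @param xi Length-2 vector of gamma precisions.
#' @param phi Shared log-mean scale, in (-10, 1).
#' @param alpha Length-2 vector in (0, 1).
#' @param theta Variance scale in (1e-4, 5).
#' @param beta Length-2 vector in (0, 1).
#' @param correlation Branch-rate correlation in (-1, 1).
#' @param log_rates E x 2 matrix of per-branch log rates.
#' @return An `evo_state` list.
#' @export
evo_state <- function(pi, xi, phi, alpha, theta, beta, correlation, log_rates) {
  log_rates <- as.matrix(log_rates)
  stopifnot(length(pi) == 2, length(xi) == 2, length(alpha) == 2,
            length(beta) == 2, ncol(log_rates) == 2)
  structure(list(pi = pi, xi = xi, phi = phi, alpha = alpha, theta = theta,
                 beta = beta, correlation = correlation, log_rates = log_rates),
            class = "evo_state")
}

pack_state <- function(state) {
  c(state$pi, state$xi, state$phi, state$alpha, state$theta, state$beta,
    state$correlation, state$log_rates[, 1], state$log_rates[, 2])
}

unpack_state <- function(v, n_branch) {
  evo_state(pi = v[1:2], xi = v[3:4], phi = v[5], alpha = v[6:7], theta = v[8],
            beta = v[9:10], correlation = v[11],
            log_rates = cbind(v[12:(11 + n_branch)],
                              v[(12 + n_branch):(11 + 2 * n_branch)]))
}

#' Draw a model state from the prior
#'
#' Samples every parameter from its prior (uniform stationary frequencies,
#' lognormal precisions, uniform `phi`, Beta proportionality and variance
#' shares, log-uniform variance scale, uniform correlation under LKJ eta = 1,
#' and bivariate-lognormal branch rates). Consumes the current RNG stream.
#'
#' @param tree A `timetree`.
#' @param variance_mode `"additive"` or `"multiplicative"` (see [run_config()]).
#' @return An `evo_state`.
#' @export
draw_prior_state <- function(tree, variance_mode = "additive") {
  E <- nrow(tree$branches)
  pi <- runif(2)
  xi <- rlnorm(2, log(5), 0.587)
  phi <- runif(1, -10, 1)
  alpha <- rbeta(2, 2, 2)
  theta <- exp(runif(1, log(1e-4), log(5)))
  beta <- rbeta(2, 10, 10)
  cc <- runif(1, -1, 1)
  mu <- phi + log(2 * alpha)
  s2 <- branch_variances(theta, beta, variance_mode)
  Sig <- diag(sqrt(s2)) %*% matrix(c(1, cc, cc, 1), 2) %*% diag(sqrt(s2))
  z <- matrix(rnorm(2 * E), E, 2) %*% chol(Sig)
  log_rates <- sweep(z, 2, mu, "+")
  evo_state(pi, xi, phi, alpha, theta, beta, cc, log_rates)
}

branch_variances <- function(theta, beta, variance_mode) {
  if (variance_mode == "additive") theta + 2 * beta else theta * 2 * beta
}

# Compress a genes x species state tibble into unique tip patterns.
compress_patterns <- function(states, tree) {
  check_states(states)
  tips <- tree$phylo$tip.label
  extra <- setdiff(setdiff(names(states), "gene"), tips)
  if (length(extra) > 0) {
    abort(paste0("species not in tree: ", paste(extra, collapse = ", ")))
  }
  m <- matrix(-1L, nrow(states), length(tips),
              dimnames = list(states$gene, tips))
  for (sp in intersect(tips, names(states))) {
    v <- states[[sp]]
    v[is.na(v)] <- -1L
    m[, sp] <- as.integer(v)
  }
  key <- apply(m, 1, paste, collapse = ",")
  u <- !duplicated(key)
  patterns <- m[u, , drop = FALSE]
  gene_index <- match(key, key[u])
  counts <- as.numeric(tabulate(gene_index, nbins = nrow(patterns)))
  list(patterns = patterns, counts = counts, gene_index = gene_index,
       genes = states$gene)
}

#' Per-gene pruning log-likelihood
#'
#' Felsenstein pruning likelihood of ternary tip states under the scaled
#' two-state chain, marginalized over the discretized-gamma rate categories
#' with equal weights, with the stationary root prior `(1 - pi, pi)`.
#' Missing tips contribute the partial likelihood (1, 1).
#'
#' @param tree A `timetree`.
#' @param tip_states Named vector (one gene) or genes x species matrix /
#'   wide tibble of 0/1/NA states.
#' @param pi Stationary ON frequency.
#' @param rates Per-branch rates, in the branch order of [branches()].
#' @param categories A [gamma_categories()] object (or `NULL` for a single
#'   unit-rate category).
#' @return Numeric vector of per-gene log-likelihoods.
#' @export
gene_log_likelihood <- function(tree, tip_states, pi, rates, categories = NULL) {
  if (is.null(categories)) categories <- gamma_categories(1, k = 1)
  if (is.null(dim(tip_states)) && !is.data.frame(tip_states)) {
    tip_states <- tibble(gene = "g1", !!!as.list(tip_states))
  } else if (!is.data.frame(tip_states)) {
    tip_states <- as_tibble(as.data.frame(tip_states), rownames = "gene")
  }
  cp <- compress_patterns(tip_states, tree)
  ta <- tree_arrays(tree)
  if (length(rates) != length(ta$elen)) abort("rates must have one entry per branch")
  rp <- .prune_root_partials(cp$patterns, ta$child, ta$parent, ta$elen,
                             ta$n_tip, as.numeric(rates), pi,
                             categories$rates)
  ll <- pattern_logliks(rp, pi, categories$k)
  unname(ll[cp$gene_index])
}

# log-likelihood per pattern from root partials: log (1/k) sum_c [(1-pi) L0c + pi L1c]
pattern_logliks <- function(rp, pi, k) {
  l0 <- rp$root_log0 + log(1 - pi)
  l1 <- rp$root_log1 + log(pi)
  m <- pmax(apply(l0, 1, max), apply(l1, 1, max))
  m[!is.finite(m)] <- 0
  log(rowSums(exp(l0 - m)) + rowSums(exp(l1 - m))) + m - log(k)
}

#' Log prior density of a model state
#'
#' Sum of the log densities of every model parameter under its prior:
#' Beta(1,1) stationary frequencies, LogNormal(ln 5, 0.587) precisions,
#' Uniform(-10, 1) `phi`, Beta(2,2) proportionality shares, LogUniform(1e-4,
#' 5) variance scale, Beta(10,10) variance shares, LKJ(eta = 1) correlation
#' (density 1/2 on (-1, 1) for two organs), and the bivariate normal density
#' of each branch's log-rate pair given `mu_i = phi + log(2 alpha_i)` and the
#' covariance implied by `variance_mode`. Returns `-Inf` outside the support.
#'
#' @param state An [evo_state()].
#' @param variance_mode `"additive"` or `"multiplicative"`.
#' @return Log prior density.
#' @export
log_prior <- function(state, variance_mode = "additive") {
  s <- state
  if (any(s$pi <= 0 | s$pi >= 1) || any(s$xi <= 0) ||
      s$phi < -10 || s$phi > 1 || any(s$alpha <= 0 | s$alpha >= 1) ||
      s$theta < 1e-4 || s$theta > 5 || any(s$beta <= 0 | s$beta >= 1) ||
      s$correlation <= -1 || s$correlation >= 1) {
    return(-Inf)
  }
  lp <- sum(dlnorm(s$xi, log(5), 0.587, log = TRUE)) +
    -log(11) +
    sum(dbeta(s$alpha, 2, 2, log = TRUE)) +
    (-log(s$theta) - log(log(5 / 1e-4))) +
    sum(dbeta(s$beta, 10, 10, log = TRUE)) +
    log(1 / 2)
  mu <- s$phi + log(2 * s$alpha)
  s2 <- branch_variances(s$theta, s$beta, variance_mode)
  cv <- s$correlation * sqrt(prod(s2))
  det <- prod(s2) - cv^2
  if (det <= 0) return(-Inf)
  x <- s$log_rates[, 1] - mu[1]
  y <- s$log_rates[, 2] - mu[2]
  q <- (s2[2] * x^2 - 2 * cv * x * y + s2[1] * y^2) / det
  lp + sum(-log(2 * base::pi) - 0.5 * log(det) - 0.5 * q)
}

#' Total log posterior of a state given discretized data
#'
#' `log_prior(state)` plus the pruning log-likelihood summed over organs and
#' genes.
#'
#' @param state An [evo_state()].
#' @param data Named list of two wide state tibbles (one per organ, in the
#'   same order as the state's organ dimension).
#' @param tree A `timetree`.
#' @param variance_mode `"additive"` or `"multiplicative"`.
#' @param k Number of gamma categories (default 6).
#' @return Log posterior density (unnormalized).
#' @export
total_log_posterior <- function(state, data, tree,
                                variance_mode = "additive", k = 6) {
  stopifnot(length(data) == 2)
  lp <- log_prior(state, variance_mode)
  if (!is.finite(lp)) return(lp)
  for (i in 1:2) {
    cats <- gamma_categories(state$xi[i], k = k)
    ll <- gene_log_likelihood(tree, data[[i]], state$pi[i],
                              exp(state$log_rates[, i]), cats)
    lp <- lp + sum(ll)
  }
  lp
}
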