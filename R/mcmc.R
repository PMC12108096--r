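#' Fit the two-organ turnover model by Metropolis-Hastings MCMC
#'
#' Samples the posterior of the correlated two-organ binary-trait model given
#' discretized expression states for both organs and a fixed time-calibrated
#' tree. The per-generation move cycle applies reflected sliding windows to
#' bounded scalars, multipliers to positive scalars, Gaussian moves to each
#' branch's log rate in each organ, a joint shift of `phi` and all log rates,
#' and a correlation walk; proposal scales are auto-tuned toward 0.23-0.44
#' acceptance during burn-in only, so detailed balance holds for the retained
#' samples. Gene rate categories are marginalized analytically (no data
#' augmentation). Identical seed and config give bitwise-identical traces.
#'
#' @param data Named list of exactly two wide state tibbles (`gene` + species
#'   columns of 0/1/NA), one per organ; names become organ labels.
#' @param tree A `timetree`; all species in `data` must be tips.
#' @param config A [run_config()].
#' @return A `turnover_fit`: list with `trace` (tibble, one row per retained
#'   sample, columns `pi_<organ>`, `xi_<organ>`, `phi`, `alpha_<organ>`,
#'   `theta`, `beta_<organ>`, `corr`, `r_<organ>_<branch>`, `log_posterior`,
#'   `log_lik`, `.chain`), `acceptance`, `organs`, `tree`, `data`, `config`,
#'   `n_samples` per chain.
#' @export
run_mcmc <- function(data, tree, config = run_config()) {
  stopifnot(inherits(tree, "timetree"), inherits(config, "run_config"))
  if (length(data) != 2) abort("data must be a named list of two organ state tables")
  organs <- names(data)
  if (is.null(organs) || any(organs == "")) organs <- c("organ1", "organ2")
  for (d in data) {
    check_states(d)
    if (nrow(d) == 0) abort("zero usable genes in data")
  }
  cp <- lapply(data, compress_patterns, tree = tree)
  ta <- tree_arrays(tree)
  E <- length(ta$elen)
  burnin <- as.integer(floor(config$generations * config$burnin_frac))

  traces <- list()
  accs <- list()
  for (ch in seq_len(config$chains)) {
    set.seed(config$seed + 100000L * (ch - 1L))
    init <- NULL
    for (try in seq_len(100)) {
      st <- draw_prior_state(tree, config$variance_mode)
      v <- pack_state(st)
      lp <- .state_log_posterior_cpp(v, cp[[1]]$patterns, cp[[1]]$counts,
                                     cp[[2]]$patterns, cp[[2]]$counts,
                                     ta$child, ta$parent, ta$elen, ta$n_tip,
                                     config$k,
                                     varmode_int(config$variance_mode))
      if (is.finite(lp[["log_posterior"]])) { init <- v; break }
    }
    if (is.null(init)) abort("could not find a finite-posterior initialization in 100 prior draws")
    scales <- c(rep(0.2, 2), rep(0.8, 2), 0.5, rep(0.2, 2), 0.8,
                rep(0.2, 2), 0.3, 0.5, 0.5, 0.3)
    res <- .mcmc_run_cpp(cp[[1]]$patterns, cp[[1]]$counts,
                         cp[[2]]$patterns, cp[[2]]$counts,
                         ta$child, ta$parent, ta$elen, ta$n_tip,
                         init, config$k, config$generations, burnin,
                         config$thin, varmode_int(config$variance_mode),
                         50L, scales)
    tr <- as_tibble(as.data.frame(res$trace))
    names(tr) <- c(paste0("pi_", organs), paste0("xi_", organs), "phi",
                   paste0("alpha_", organs), "theta", paste0("beta_", organs),
                   "corr",
                   paste0("r_", organs[1], "_", seq_len(E)),
                   paste0("r_", organs[2], "_", seq_len(E)),
                   "log_posterior", "log_lik")
    tr$.chain <- ch
    traces[[ch]] <- tr
    accs[[ch]] <- tibble(
      chain = ch,
      move = c(paste0("slide_pi_", organs), paste0("mult_xi_", organs),
               "slide_phi", paste0("slide_alpha_", organs), "mult_theta",
               paste0("slide_beta_", organs), "slide_corr",
               paste0("branch_rate_", organs), "joint_shift"),
      acceptance = as.numeric(res$acceptance))
  }
  structure(list(trace = bind_rows(traces), acceptance = bind_rows(accs),
                 organs = organs, tree = tree, data = data, patterns = cp,
                 config = config,
                 n_samples = as.integer((config$generations - burnin) %/% config$thin),
                 burnin = burnin),
            class = "turnover_fit")
}

varmode_int <- function(mode) if (mode == "additive") 0L else 1L

#' @export
print.turnover_fit <- function(x, ...) {
  cat("<turnover_fit> organs: ", paste(x$organs, collapse = ", "),
      "; ", x$config$chains, " chain(s) x ", x$n_samples, " samples; ",
      length(unique(unlist(lapply(x$data, function(d) d$gene)))), " genes\n",
      sep = "")
  invisible(x)
}

#' Potential scale reduction factor (Gelman-Rubin)
#'
#' Classic between/within-chain variance diagnostic; values close to 1 and
#' below 1.2 indicate convergence. With chains that are exact copies the
#' between-chain variance is zero and the statistic reduces to
#' `sqrt((n-1)/n)`.
#'
#' @param chains A list of numeric vectors (>= 2 chains, equal lengths
#'   >= 10), or a matrix with one column per chain.
#' @return The PSRF.
#' @export
psrf <- function(chains) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)), function(j) chains[, j])
  m <- length(chains)
  if (m < 2) abort("psrf needs >= 2 chains")
  n <- unique(lengths(chains))
  if (length(n) != 1) abort("chains must have equal lengths")
  if (n < 10) abort("chains must have length >= 10")
  means <- vapply(chains, mean, numeric(1))
  W <- mean(vapply(chains, var, numeric(1)))
  B <- n * var(means)
  v_hat <- (n - 1) / n * W + B / n
  sqrt(v_hat / W)
}

#' Effective sample size
#'
#' `n / (1 + 2 sum(rho_t))` with the autocorrelation sum truncated by the
#' initial-positive-sequence rule (stop at the first lag pair whose summed
#' autocorrelation is non-positive). A constant series has no information
#' and returns 0 with a warning.
#'
#' @param series Numeric vector of length >= 10.
#' @return Effective sample size.
#' @export
ess <- function(series) {
  n <- length(series)
  if (n < 10) abort("series must have length >= 10")
  if (var(series) == 0) {
    warn("constant series: effective sample size is 0")
    return(0)
  }
  rho <- acf(series, lag.max = n - 1, plot = FALSE)$acf[-1]
  s <- 0
  t <- 1
  while (t <= length(rho)) {
    pair <- rho[t] + if (t + 1 <= length(rho)) rho[t + 1] else 0
    if (pair <= 0) break
    s <- s + pair
    t <- t + 2
  }
  n / (1 + 2 * s)
}

#' Convergence diagnostics for a fit
#'
#' Per-parameter effective sample size (pooled within chains) and, when the
#' fit has >= 2 chains, the Gelman-Rubin PSRF.
#'
#' @param fit A `turnover_fit`.
#' @param parameters Columns to diagnose (default: all scalar parameters).
#' @return Tibble `parameter`, `ess`, `psrf`.
#' @export
diagnostics <- function(fit, parameters = NULL) {
  stopifnot(inherits(fit, "turnover_fit"))
  tr <- fit$trace
  if (is.null(parameters)) {
    parameters <- setdiff(names(tr), c("log_posterior", "log_lik", ".chain"))
  }
  chains <- split(tr, tr$.chain)
  bind_rows(lapply(parameters, function(p) {
    e <- sum(vapply(chains, function(cc) {
      if (var(cc[[p]]) == 0) 0 else ess(cc[[p]])
    }, numeric(1)))
    r <- if (length(chains) >= 2) {
      vals <- lapply(chains, function(cc) cc[[p]])
      if (all(vapply(vals, var, numeric(1)) == 0)) NA_real_ else psrf(vals)
    } else NA_real_
    tibble(parameter = p, ess = e, psrf = r)
  }))
}
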