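trace_draw_index <- function(fit, max_draws) {
  n <- nrow(fit$trace)
  unique(round(seq(1, n, length.out = min(max_draws, n))))
}

trace_rate_matrix <- function(fit, organ) {
  E <- nrow(fit$tree$branches)
  as.matrix(fit$trace[, paste0("r_", organ, "_", seq_len(E))])
}

# row-wise log of (1-pi) exp(l0) + pi exp(l1), numerically stable
root_mix_log <- function(l0, l1, pi) {
  m <- pmax(apply(l0, 1, max), apply(l1, 1, max))
  m[!is.finite(m)] <- 0
  list(m = m,
       on = pi * rowSums(exp(l1 - m)),
       off = (1 - pi) * rowSums(exp(l0 - m)))
}

#' Posterior gene-specific turnover rates
#'
#' For each retained MCMC sample, the posterior over a gene's rate category
#' is proportional to `(1/k) L_c` (the pruning likelihood at category rate
#' `a_c`); the gene's relative rate is the category-posterior-weighted mean
#' of the `a_c`, and its expected number of turnover events over the tree is
#' that rate times `sum_b r_b l_b` (valid because the normalized rate matrix
#' has unit mean flow at stationarity). Both are averaged over the trace.
#'
#' @param fit A `turnover_fit`.
#' @param max_draws Number of evenly spaced trace samples to use.
#' @return A `gene_rates` object: `summary` tibble (`organ`, `gene`,
#'   `mean_rate`, `expected_events`), `draws` (per organ, genes x samples
#'   matrix of rates), `branch_flow` (per organ, per-sample `sum_b r_b l_b`).
#' @export
gene_posterior_rates <- function(fit, max_draws = 200) {
  stopifnot(inherits(fit, "turnover_fit"))
  if (nrow(fit$trace) == 0) abort("empty trace")
  idx <- trace_draw_index(fit, max_draws)
  ta <- tree_arrays(fit$tree)
  elen <- ta$elen
  draws <- list(); flows <- list(); summ <- list()
  for (organ in fit$organs) {
    cp <- fit$patterns[[match(organ, fit$organs)]]
    rates_mat <- trace_rate_matrix(fit, organ)
    xi_v <- fit$trace[[paste0("xi_", organ)]]
    pi_v <- fit$trace[[paste0("pi_", organ)]]
    G <- length(cp$gene_index)
    rmat <- matrix(0, G, length(idx))
    flow <- numeric(length(idx))
    for (s in seq_along(idx)) {
      j <- idx[s]
      cats <- gamma_categories(xi_v[j], k = fit$config$k)
      rp <- .prune_root_partials(cp$patterns, ta$child, ta$parent, elen,
                                 ta$n_tip, rates_mat[j, ], pi_v[j],
                                 cats$rates)
      l0 <- rp$root_log0 + log(1 - pi_v[j])
      l1 <- rp$root_log1 + log(pi_v[j])
      lc <- pmax(l0, l1) + log(exp(l0 - pmax(l0, l1)) + exp(l1 - pmax(l0, l1)))
      w <- exp(lc - apply(lc, 1, max))
      post <- w / rowSums(w)
      rate_p <- as.numeric(post %*% cats$rates)
      rmat[, s] <- rate_p[cp$gene_index]
      flow[s] <- sum(rates_mat[j, ] * elen)
    }
    draws[[organ]] <- rmat
    flows[[organ]] <- flow
    summ[[organ]] <- tibble(organ = organ, gene = cp$genes,
                            mean_rate = rowMeans(rmat),
                            expected_events = as.numeric(rmat %*% flow) / length(flow))
  }
  structure(list(summary = bind_rows(summ), draws = draws,
                 branch_flow = flows, organs = fit$organs,
                 genes = fit$patterns[[1]]$genes, draw_index = idx),
            class = "gene_rates")
}

#' Cumulative turnover concentration curve
#'
#' Ranks genes from fastest to slowest by expected turnover events and
#' accumulates the normalized event mass: the curve gives the fraction of
#' all turnover explained by each top fraction of genes. Under equal rates
#' it equals the diagonal; concentration of turnover in few genes bows it
#' upward (it is non-decreasing, concave, and bounded by the diagonal and 1).
#'
#' @param x A `gene_rates` object or a tibble with columns `organ`, `gene`,
#'   `expected_events`.
#' @return Tibble `organ`, `frac_genes`, `frac_events` (starting at (0, 0)).
#' @export
cumulative_turnover_curve <- function(x) {
  tb <- if (inherits(x, "gene_rates")) x$summary else x
  if (!"organ" %in% names(tb)) tb$organ <- "all"
  if (nrow(tb) == 0) abort("no genes supplied")
  bind_rows(lapply(split(tb, tb$organ), function(d) {
    e <- sort(d$expected_events, decreasing = TRUE)
    if (all(e == 0)) abort("all expected events are zero; curve undefined")
    n <- length(e)
    tibble(organ = d$organ[1], frac_genes = c(0, seq_len(n) / n),
           frac_events = c(0, cumsum(e) / sum(e)))
  }))
}

#' Percent difference of mean rate (PDMR) between gene groups
#'
#' For each retained sample, `PDMR = (mean focal rate - mean reference rate)
#' / mean reference rate * 100`. The posterior sample of PDMR quantifies how
#' much faster (positive) or slower (negative) the focal group turns over
#' relative to the reference; it is invariant to rescaling all gene rates.
#'
#' @param gr A [gene_posterior_rates()] result.
#' @param focal Character vector of focal gene ids.
#' @param reference Reference gene ids (default: all other genes).
#' @return A `pdmr_result`: `draws` tibble (`organ`, `draw`, `pdmr`) and
#'   `summary` tibble (`organ`, `m_pdmr`, `conf.low`, `conf.high`,
#'   `n_focal`, `n_reference`).
#' @export
pdmr <- function(gr, focal, reference = NULL) {
  stopifnot(inherits(gr, "gene_rates"))
  genes <- gr$genes
  if (is.null(reference)) reference <- setdiff(genes, focal)
  fi <- match(focal, genes); ri <- match(reference, genes)
  if (length(fi) == 0 || anyNA(fi)) abort("focal group empty or has unknown genes")
  if (length(ri) == 0 || anyNA(ri)) abort("reference group empty or has unknown genes")
  dr <- list(); sm <- list()
  for (organ in gr$organs) {
    m <- gr$draws[[organ]]
    v <- 100 * (colMeans(m[fi, , drop = FALSE]) /
                  colMeans(m[ri, , drop = FALSE]) - 1)
    dr[[organ]] <- tibble(organ = organ, draw = seq_along(v), pdmr = v)
    ci <- quantile(v, c(0.025, 0.975), names = FALSE)
    sm[[organ]] <- tibble(organ = organ, m_pdmr = mean(v),
                          conf.low = ci[1], conf.high = ci[2],
                          n_focal = length(fi), n_reference = length(ri))
  }
  structure(list(draws = bind_rows(dr), summary = bind_rows(sm)),
            class = "pdmr_result")
}

#' Random-partition null for the mean PDMR
#'
#' Builds the empirical null of the mean PDMR (M-PDMR): genes are split into
#' random focal/reference groups of the observed sizes, and each partition
#' is summarized by its posterior-mean PDMR. The tail probability of an
#' observed M-PDMR against this null calibrates how surprising a group's
#' rate difference is.
#'
#' @param gr A [gene_posterior_rates()] result.
#' @param n_focal Size of the random focal group.
#' @param n_partitions Number of random partitions (default 1000).
#' @param seed Optional integer seed.
#' @return Tibble `organ`, `partition`, `m_pdmr`.
#' @export
mpdmr_null <- function(gr, n_focal, n_partitions = 1000, seed = NULL) {
  stopifnot(inherits(gr, "gene_rates"))
  if (n_partitions < 1) abort("n_partitions must be >= 1")
  n <- length(gr$genes)
  if (n_focal < 1 || n_focal >= n) abort("n_focal must be in [1, n_genes)")
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  sel <- replicate(n_partitions, sample.int(n, n_focal), simplify = FALSE)
  for (organ in gr$organs) {
    m <- gr$draws[[organ]]
    tot <- colSums(m)
    v <- vapply(sel, function(fi) {
      mf <- colMeans(m[fi, , drop = FALSE])
      mr <- (tot - colSums(m[fi, , drop = FALSE])) / (n - n_focal)
      mean(100 * (mf / mr - 1))
    }, numeric(1))
    out[[organ]] <- tibble(organ = organ, partition = seq_len(n_partitions),
                           m_pdmr = v)
  }
  bind_rows(out)
}

#' Empirical tail probability of an observed M-PDMR
#'
#' Upper-tail rank probability `(1 + #\{null >= observed\}) / (1 + N)`;
#' under the null (focal group chosen at random) it is uniform on a fine
#' grid of (0, 1).
#'
#' @param observed Observed M-PDMR.
#' @param null Numeric vector of null M-PDMR values (one organ).
#' @return Tail probability in (0, 1\].
#' @export
pdmr_tail_probability <- function(observed, null) {
  (1 + sum(null >= observed)) / (1 + length(null))
}

#' Marginal posterior probability of the ON state at the root
#'
#' For each gene and retained sample, `P(root = ON | data)` under the fitted
#' model (category-weighted root posterior with stationary root prior),
#' averaged over the trace. Also summarizes the fraction of genes whose
#' posterior exceeds a probability cutoff in either direction.
#'
#' @param fit A `turnover_fit`.
#' @param max_draws Number of evenly spaced trace samples to use.
#' @param cutoff Reporting cutoff (default 0.95).
#' @return An `ancestral_root` object: `genes` tibble (`organ`, `gene`,
#'   `p_root_on`) and `summary` tibble (`organ`, `cutoff`, `frac_on`,
#'   `frac_off`).
#' @export
ancestral_root_marginal <- function(fit, max_draws = 200, cutoff = 0.95) {
  stopifnot(inherits(fit, "turnover_fit"))
  if (nrow(fit$trace) == 0) abort("empty trace")
  idx <- trace_draw_index(fit, max_draws)
  ta <- tree_arrays(fit$tree)
  genes_tb <- list(); summ <- list()
  for (organ in fit$organs) {
    cp <- fit$patterns[[match(organ, fit$organs)]]
    rates_mat <- trace_rate_matrix(fit, organ)
    xi_v <- fit$trace[[paste0("xi_", organ)]]
    pi_v <- fit$trace[[paste0("pi_", organ)]]
    acc <- numeric(nrow(cp$patterns))
    for (s in idx) {
      cats <- gamma_categories(xi_v[s], k = fit$config$k)
      rp <- .prune_root_partials(cp$patterns, ta$child, ta$parent, ta$elen,
                                 ta$n_tip, rates_mat[s, ], pi_v[s],
                                 cats$rates)
      mix <- root_mix_log(rp$root_log0, rp$root_log1, pi_v[s])
      acc <- acc + mix$on / (mix$on + mix$off)
    }
    p <- (acc / length(idx))[cp$gene_index]
    genes_tb[[organ]] <- tibble(organ = organ, gene = cp$genes, p_root_on = p)
    summ[[organ]] <- tibble(organ = organ, cutoff = cutoff,
                            frac_on = mean(p > cutoff),
                            frac_off = mean(1 - p > cutoff))
  }
  structure(list(genes = bind_rows(genes_tb), summary = bind_rows(summ)),
            class = "ancestral_root")
}

#' Joint posterior of root state and a focal tip state
#'
#' Per gene, the posterior probability that the gene was OFF at the root and
#' ON at a focal tip (`tip_state = "on"`: an expression gain on that tip's
#' lineage), or OFF at both (`tip_state = "off"`). Computed by clamping the
#' focal tip to the requested state (zero partial likelihood for the other
#' state) and reading the root-OFF posterior mass, renormalized by the
#' unclamped marginal likelihood. A tip observed in the opposite state gives
#' probability 0; for an observed matching state this reduces to the root
#' marginal.
#'
#' @param fit A `turnover_fit`.
#' @param focal_tip Tip label present in the tree.
#' @param tip_state Clamped tip state, `"on"` (default) or `"off"`.
#' @param max_draws Number of evenly spaced trace samples to use.
#' @param cutoff Reporting cutoff (default 0.95).
#' @return A `joint_root_tip` object: `genes` tibble (`organ`, `gene`,
#'   `p_joint`) and `summary` tibble (`organ`, `cutoff`, `n_above`).
#' @export
joint_root_tip_gain <- function(fit, focal_tip, tip_state = c("on", "off"),
                                max_draws = 200, cutoff = 0.95) {
  stopifnot(inherits(fit, "turnover_fit"))
  tip_state <- match.arg(tip_state)
  tips <- fit$tree$phylo$tip.label
  if (!focal_tip %in% tips) abort(paste0("unknown tip label: ", focal_tip))
  clamp_val <- if (tip_state == "on") 1L else 0L
  idx <- trace_draw_index(fit, max_draws)
  ta <- tree_arrays(fit$tree)
  genes_tb <- list(); summ <- list()
  for (organ in fit$organs) {
    cp <- fit$patterns[[match(organ, fit$organs)]]
    obs <- cp$patterns[, focal_tip]
    clamped <- cp$patterns
    clamped[, focal_tip] <- clamp_val
    rates_mat <- trace_rate_matrix(fit, organ)
    xi_v <- fit$trace[[paste0("xi_", organ)]]
    pi_v <- fit$trace[[paste0("pi_", organ)]]
    acc <- numeric(nrow(cp$patterns))
    for (s in idx) {
      cats <- gamma_categories(xi_v[s], k = fit$config$k)
      rp <- .prune_root_partials(cp$patterns, ta$child, ta$parent, ta$elen,
                                 ta$n_tip, rates_mat[s, ], pi_v[s], cats$rates)
      rpc <- .prune_root_partials(clamped, ta$child, ta$parent, ta$elen,
                                  ta$n_tip, rates_mat[s, ], pi_v[s], cats$rates)
      mix <- root_mix_log(rp$root_log0, rp$root_log1, pi_v[s])
      # clamped root-OFF mass on the same per-row log scale as the marginal
      num <- (1 - pi_v[s]) * rowSums(exp(rpc$root_log0 - mix$m))
      acc <- acc + num / (mix$on + mix$off)
    }
    p <- acc / length(idx)
    p[obs == (1L - clamp_val)] <- 0  # observed opposite state
    p <- p[cp$gene_index]
    genes_tb[[organ]] <- tibble(organ = organ, gene = cp$genes, p_joint = p)
    summ[[organ]] <- tibble(organ = organ, cutoff = cutoff,
                            n_above = sum(p > cutoff))
  }
  structure(list(genes = bind_rows(genes_tb), summary = bind_rows(summ),
                 focal_tip = focal_tip, tip_state = tip_state),
            class = "joint_root_tip")
}

#' Leave-k-out cross-validation of tip-state predictions
#'
#' Holds out a random fraction of observed (gene, species, organ) cells by
#' setting them to missing, refits the model, and predicts each withheld
#' state from its gene's remaining tips by tip-clamping: `P(tip = ON | rest)
#' = L(cell = ON) / L(cell = missing)`, averaged over the trace. Accuracy is
#' reported two ways: the mean posterior probability assigned to the
#' withheld call, and the argmax agreement rate (overall and per species).
#'
#' @param data Named list of two wide state tibbles.
#' @param tree A `timetree`.
#' @param config A [run_config()] used for the refit.
#' @param holdout_fraction Fraction of observed cells to withhold, in (0, 1).
#' @param seed Integer seed for the holdout draw.
#' @param max_draws Number of trace samples for the predictive average.
#' @return An `xval_result`: `cells` tibble (`organ`, `gene`, `species`,
#'   `true_state`, `p_on`, `p_true`, `correct`), `summary` tibble
#'   (`mean_p_true`, `agreement`, `majority_baseline`, `n_cells`),
#'   `per_species` tibble, and the refit `fit`.
#' @export
leave_k_out_xval <- function(data, tree, config = run_config(),
                             holdout_fraction = 0.05, seed = 1L,
                             max_draws = 100) {
  if (holdout_fraction <= 0 || holdout_fraction >= 1) {
    abort("holdout_fraction must be in (0, 1)")
  }
  set.seed(seed)
  organs <- names(data)
  cells <- list()
  for (o in organs) {
    st <- data[[o]]
    for (sp in setdiff(names(st), "gene")) {
      ok <- which(!is.na(st[[sp]]))
      if (length(ok) > 0) {
        cells[[paste(o, sp)]] <- tibble(organ = o, species = sp, row = ok,
                                        gene = st$gene[ok],
                                        true_state = st[[sp]][ok])
      }
    }
  }
  cells <- bind_rows(cells)
  n_hold <- ceiling(holdout_fraction * nrow(cells))
  hold <- cells[sample.int(nrow(cells), n_hold), ]
  masked <- data
  for (i in seq_len(nrow(hold))) {
    masked[[hold$organ[i]]][[hold$species[i]]][hold$row[i]] <- NA_integer_
  }
  # genes emptied across all species in both organs cannot be predicted
  empty <- vapply(unique(hold$gene), function(g) {
    all(vapply(organs, function(o) {
      r <- match(g, masked[[o]]$gene)
      all(is.na(as.integer(masked[[o]][r, setdiff(names(masked[[o]]), "gene")])))
    }, logical(1)))
  }, logical(1))
  if (any(empty)) {
    bad <- unique(hold$gene)[empty]
    warn(paste0(length(bad), " gene(s) fully emptied by the holdout were excluded"))
    for (i in which(hold$gene %in% bad)) {
      masked[[hold$organ[i]]][[hold$species[i]]][hold$row[i]] <- hold$true_state[i]
    }
    hold <- hold[!hold$gene %in% bad, ]
  }
  fit <- run_mcmc(masked, tree, config)
  idx <- trace_draw_index(fit, max_draws)
  ta <- tree_arrays(tree)
  hold$p_on <- NA_real_
  for (o in organs) {
    hi <- which(hold$organ == o)
    if (length(hi) == 0) next
    cp <- fit$patterns[[match(o, organs)]]
    gidx <- cp$gene_index[match(hold$gene[hi], cp$genes)]
    pat_miss <- cp$patterns[gidx, , drop = FALSE]
    pat_on <- pat_miss
    for (j in seq_along(hi)) pat_on[j, hold$species[hi[j]]] <- 1L
    rates_mat <- trace_rate_matrix(fit, o)
    xi_v <- fit$trace[[paste0("xi_", o)]]
    pi_v <- fit$trace[[paste0("pi_", o)]]
    acc <- numeric(length(hi))
    for (s in idx) {
      cats <- gamma_categories(xi_v[s], k = fit$config$k)
      rp_m <- .prune_root_partials(pat_miss, ta$child, ta$parent, ta$elen,
                                   ta$n_tip, rates_mat[s, ], pi_v[s], cats$rates)
      rp_on <- .prune_root_partials(pat_on, ta$child, ta$parent, ta$elen,
                                    ta$n_tip, rates_mat[s, ], pi_v[s], cats$rates)
      mix_m <- root_mix_log(rp_m$root_log0, rp_m$root_log1, pi_v[s])
      on_num <- pi_v[s] * rowSums(exp(rp_on$root_log1 - mix_m$m)) +
        (1 - pi_v[s]) * rowSums(exp(rp_on$root_log0 - mix_m$m))
      acc <- acc + pmin(1, on_num / (mix_m$on + mix_m$off))
    }
    hold$p_on[hi] <- acc / length(idx)
  }
  hold$p_true <- ifelse(hold$true_state == 1L, hold$p_on, 1 - hold$p_on)
  hold$correct <- (hold$p_on > 0.5) == (hold$true_state == 1L)
  maj <- max(mean(hold$true_state == 1L), mean(hold$true_state == 0L))
  summary <- tibble(mean_p_true = mean(hold$p_true),
                    agreement = mean(hold$correct),
                    majority_baseline = maj, n_cells = nrow(hold))
  per_species <- hold |>
    group_by(.data$species) |>
    summarise(mean_p_true = mean(.data$p_true),
              agreement = mean(.data$correct), n_cells = n(),
              .groups = "drop")
  structure(list(cells = select(hold, -"row"), summary = summary,
                 per_species = per_species, fit = fit),
            class = "xval_result")
}

#' Highest posterior density interval
#'
#' Shortest interval containing a given posterior mass.
#'
#' @param x Numeric sample.
#' @param prob Mass to cover (default 0.95).
#' @return Length-2 vector (lower, upper).
#' @export
hpd_interval <- function(x, prob = 0.95) {
  x <- sort(x)
  n <- length(x)
  m <- max(1, ceiling(prob * n))
  if (m >= n) return(c(x[1], x[n]))
  w <- x[(m + 1):n] - x[1:(n - m)]
  i <- which.min(w)
  c(x[i], x[i + m])
}

#' Posterior summaries of branch-specific turnover rates
#'
#' Per branch and organ: posterior mean, median and 95% HPD of the branch
#' rate; per organ: the time-weighted mean rate `sum_b r_b l_b / sum_b l_b`
#' computed per sample and then summarized. With equal branch lengths the
#' organ mean reduces to the simple average of branch rates.
#'
#' @param fit A `turnover_fit`.
#' @param prob HPD mass (default 0.95).
#' @return A `branch_rates` object: `branches` tibble (`organ`, `branch`,
#'   `length`, `label`, `terminal`, `mean`, `median`, `hpd_lower`,
#'   `hpd_upper`) and `organ_mean` tibble (`organ`, `mean`, `median`,
#'   `hpd_lower`, `hpd_upper`).
#' @export
branch_rate_summary <- function(fit, prob = 0.95) {
  stopifnot(inherits(fit, "turnover_fit"))
  br <- fit$tree$branches
  res <- list(); om <- list()
  for (organ in fit$organs) {
    m <- trace_rate_matrix(fit, organ)
    h <- apply(m, 2, hpd_interval, prob = prob)
    res[[organ]] <- tibble(organ = organ, branch = br$branch,
                           length = br$length, label = br$label,
                           terminal = br$terminal,
                           mean = unname(colMeans(m)),
                           median = unname(apply(m, 2, median)),
                           hpd_lower = h[1, ], hpd_upper = h[2, ])
    tw <- as.numeric(m %*% br$length) / sum(br$length)
    hh <- hpd_interval(tw, prob)
    om[[organ]] <- tibble(organ = organ, mean = mean(tw), median = median(tw),
                          hpd_lower = hh[1], hpd_upper = hh[2])
  }
  structure(list(branches = bind_rows(res), organ_mean = bind_rows(om)),
            class = "branch_rates")
}
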