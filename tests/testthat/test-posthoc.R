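test_that("gene rates are exactly 1 under a degenerate mixture and prior weights when unobserved", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  E <- nrow(branches(tr))
  obs <- states_from_matrix(matrix(c(1L, NA, 0L, NA, 1L, NA), 2, 3), tr)
  # gene 2 is entirely missing
  data <- list(a = obs, b = obs)
  fit1 <- manual_fit(tr, data, pi = c(0.6, 0.6),
                     rates_by_organ = list(rep(0.1, E), rep(0.1, E)), k = 1)
  gr1 <- gene_posterior_rates(fit1)
  expect_true(all(gr1$summary$mean_rate == 1))

  fit6 <- manual_fit(tr, data, pi = c(0.6, 0.6),
                     rates_by_organ = list(rep(0.1, E), rep(0.1, E)), k = 6)
  gr6 <- gene_posterior_rates(fit6)
  missing_gene <- dplyr::filter(gr6$summary, gene == "g002")
  expect_equal(missing_gene$mean_rate, rep(1, 2), tolerance = 1e-8)
  # expected events = rate * sum r l
  flow <- sum(0.1 * branches(tr)$length)
  expect_equal(missing_gene$expected_events, rep(flow, 2), tolerance = 1e-8)
})

test_that("fast simulated genes get higher posterior rates than slow genes", {
  tr <- example_tree()
  sim <- fast_subset_scenario(tr, 400, rate = 0.002, fast_fraction = 0.05,
                              seed = 81)
  fit <- run_mcmc(sim$states, tr, run_config(generations = 600, thin = 5, seed = 82))
  gr <- gene_posterior_rates(fit, max_draws = 60)
  s <- dplyr::filter(gr$summary, organ == fit$organs[1])
  expect_gt(mean(s$mean_rate[sim$fast_genes]), mean(s$mean_rate[-sim$fast_genes]))
})

test_that("cumulative turnover curve has the documented geometry", {
  eq <- tibble::tibble(organ = "a", gene = paste0("g", 1:10),
                       expected_events = rep(2, 10))
  cv <- cumulative_turnover_curve(eq)
  expect_equal(cv$frac_events, cv$frac_genes, tolerance = 1e-12)
  # half the genes explain half the events under equal rates
  expect_equal(cv$frac_events[cv$frac_genes == 0.5], 0.5)

  two <- tibble::tibble(organ = "a", gene = c("g1", "g2"),
                        expected_events = c(3, 1))
  cv2 <- cumulative_turnover_curve(two)
  expect_equal(cv2$frac_events, c(0, 0.75, 1))
  expect_equal(cv2$frac_genes, c(0, 0.5, 1))

  set.seed(91)
  rnd <- tibble::tibble(organ = "a", gene = paste0("g", 1:50),
                        expected_events = rlnorm(50))
  cvr <- cumulative_turnover_curve(rnd)
  expect_true(all(diff(cvr$frac_events) >= 0))
  expect_true(all(diff(diff(cvr$frac_events)) < 1e-12))  # concave
  expect_true(all(cvr$frac_events >= cvr$frac_genes - 1e-12))
  expect_true(all(cvr$frac_events <= 1 + 1e-12))

  zero <- tibble::tibble(organ = "a", gene = "g1", expected_events = 0)
  expect_error(cumulative_turnover_curve(zero), "zero")
})

test_that("PDMR obeys its algebraic identities", {
  set.seed(101)
  m <- matrix(rlnorm(100 * 20), 100, 20,
              dimnames = list(sprintf("g%03d", 1:100), NULL))
  gr <- manual_gene_rates(list(a = m, b = m * 2))
  focal <- sprintf("g%03d", 1:30)
  ref <- sprintf("g%03d", 31:100)

  # identical groups: exactly zero
  same <- pdmr(gr, focal, focal)
  expect_true(all(same$draws$pdmr == 0))

  # plug-in example: focal mean 1.2, reference mean 1.0 -> +20
  m2 <- matrix(c(rep(1.2, 5), rep(1.0, 5)), 10, 1,
               dimnames = list(paste0("g", 1:10), NULL))
  gr2 <- manual_gene_rates(list(a = m2, b = m2))
  expect_equal(pdmr(gr2, paste0("g", 1:5))$summary$m_pdmr, rep(20, 2),
               tolerance = 1e-12)

  # scale invariance
  p1 <- pdmr(gr, focal, ref)$draws$pdmr
  gr7 <- manual_gene_rates(list(a = m * 7, b = m * 14))
  expect_equal(pdmr(gr7, focal, ref)$draws$pdmr, p1, tolerance = 1e-10)

  # antisymmetry under group swap
  pswap <- pdmr(gr, ref, focal)$draws$pdmr
  expect_equal(pswap, -p1 / (1 + p1 / 100), tolerance = 1e-8)

  expect_error(pdmr(gr, character(0)), "focal")
  expect_error(pdmr(gr, "not_a_gene"), "focal")
})

test_that("the M-PDMR null has the requested size and is seed-stable", {
  set.seed(103)
  m <- matrix(rlnorm(60 * 10), 60, 10)
  gr <- manual_gene_rates(list(a = m, b = m))
  null1 <- mpdmr_null(gr, n_focal = 15, n_partitions = 50, seed = 7)
  expect_equal(nrow(null1), 100)  # 50 per organ
  expect_identical(null1, mpdmr_null(gr, n_focal = 15, n_partitions = 50, seed = 7))
  expect_error(mpdmr_null(gr, n_focal = 15, n_partitions = 0), "n_partitions")
  expect_error(mpdmr_null(gr, n_focal = 60), "n_focal")

  p <- pdmr_tail_probability(0, c(-1, 1, 2))
  expect_equal(p, 3 / 4)
})

test_that("root marginals reduce to the stationary prior without data and match enumeration", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  E <- nrow(branches(tr))
  miss <- missing_states(tr, 3)
  fitm <- manual_fit(tr, list(a = miss, b = miss), pi = c(0.37, 0.81),
                     rates_by_organ = list(rep(0.05, E), rep(0.05, E)))
  anc <- ancestral_root_marginal(fitm, max_draws = 10)
  expect_equal(anc$genes$p_root_on[anc$genes$organ == "a"], rep(0.37, 3),
               tolerance = 1e-12)
  expect_equal(anc$genes$p_root_on[anc$genes$organ == "b"], rep(0.81, 3),
               tolerance = 1e-12)

  # enumeration oracle on a 2-tip tree, both tips ON, k = 1
  t2 <- read_newick("(A:0.4,B:0.4);")
  obs2 <- states_from_matrix(matrix(1L, 1, 2), t2)
  pi <- 0.3; rates <- c(0.8, 1.3)
  fit2 <- manual_fit(t2, list(a = obs2, b = obs2), pi = c(pi, pi),
                     rates_by_organ = list(rates, rates), k = 1)
  anc2 <- ancestral_root_marginal(fit2)
  oracle <- brute_lik(t2, c(A = 1L, B = 1L), pi, rates, 1, root_fix = 1) /
    brute_lik(t2, c(A = 1L, B = 1L), pi, rates, 1)
  expect_equal(anc2$genes$p_root_on[1], oracle, tolerance = 1e-10)

  # zero-rate limit with observed ON tips: the root must be ON
  fit0 <- manual_fit(t2, list(a = obs2, b = obs2), pi = c(pi, pi),
                     rates_by_organ = list(rep(1e-9, 2), rep(1e-9, 2)), k = 1)
  expect_gt(ancestral_root_marginal(fit0)$genes$p_root_on[1], 1 - 1e-6)
})

test_that("joint root-tip probabilities have the complement and coherence identities", {
  t3 <- read_newick("((A:1,B:1):1,C:2);")
  E <- nrow(branches(t3))
  pi <- 0.45; rates <- rep(0.3, E)
  # gene 1: A observed ON; gene 2: A observed OFF; gene 3: A missing
  m <- matrix(c(1L, 0L, NA, 1L, 1L, 1L, 0L, 0L, 0L), 3, 3)
  obs <- states_from_matrix(m, t3)
  fit <- manual_fit(t3, list(a = obs, b = obs), pi = c(pi, pi),
                    rates_by_organ = list(rates, rates), k = 2)
  anc <- ancestral_root_marginal(fit)
  jon <- joint_root_tip_gain(fit, "A", "on")
  joff <- joint_root_tip_gain(fit, "A", "off")
  pa <- anc$genes[anc$genes$organ == "a", ]
  ja <- jon$genes[jon$genes$organ == "a", ]
  fa <- joff$genes[joff$genes$organ == "a", ]
  # observed OFF tip cannot have gained expression
  expect_equal(ja$p_joint[2], 0)
  # observed ON tip: joint equals the root-OFF marginal
  expect_equal(ja$p_joint[1], 1 - pa$p_root_on[1], tolerance = 1e-12)
  # missing tip: clamped states partition the root-OFF mass
  expect_equal(ja$p_joint[3] + fa$p_joint[3], 1 - pa$p_root_on[3],
               tolerance = 1e-10)

  # enumeration oracle for the missing-tip joint
  cats <- gamma_categories(5, k = 2)$rates
  tips3 <- c(A = NA, B = 1L, C = 0L)
  num <- brute_lik(t3, c(A = 1L, B = 1L, C = 0L), pi, rates, cats, root_fix = 0)
  den <- brute_lik(t3, tips3, pi, rates, cats)
  expect_equal(ja$p_joint[3], num / den, tolerance = 1e-10)

  expect_error(joint_root_tip_gain(fit, "Z"), "unknown tip")
})

test_that("HPD intervals are shortest and match normal quantiles", {
  expect_equal(hpd_interval(rep(3, 100)), c(3, 3))
  set.seed(111)
  x <- rnorm(10000)
  h <- hpd_interval(x, 0.95)
  expect_lt(abs(h[1] + 1.96), 0.05)
  expect_lt(abs(h[2] - 1.96), 0.05)
})

test_that("branch rate summaries collapse for constant traces and average with equal lengths", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  E <- nrow(branches(tr))
  obs <- states_from_matrix(matrix(1L, 2, 3), tr)
  r1 <- c(0.1, 0.2, 0.3, 0.4, 0.5)[seq_len(E)]
  fit <- manual_fit(tr, list(a = obs, b = obs), pi = c(0.5, 0.5),
                    rates_by_organ = list(r1, r1 * 2))
  bs <- branch_rate_summary(fit)
  expect_equal(bs$branches$mean[bs$branches$organ == "a"], r1)
  expect_equal(bs$branches$hpd_lower, bs$branches$hpd_upper)
  tw <- sum(r1 * branches(tr)$length) / sum(branches(tr)$length)
  expect_equal(bs$organ_mean$mean[1], tw)

  # equal branch lengths: organ mean is the simple average of branch rates
  te <- suppressWarnings(read_newick("((A:1,B:1):1,C:1);"))
  obse <- states_from_matrix(matrix(1L, 2, 3), te)
  re <- c(0.1, 0.2, 0.3, 0.4)
  fite <- manual_fit(te, list(a = obse, b = obse), pi = c(0.5, 0.5),
                     rates_by_organ = list(re, re))
  expect_equal(branch_rate_summary(fite)$organ_mean$mean[1], mean(re))
})

test_that("leave-k-out holdouts are seed-stable and calibrated on simulated data", {
  env <- small_fit()
  sim <- env$sim
  tr <- sim$tree
  cfg <- run_config(generations = 800, thin = 5, seed = 121)
  xv1 <- leave_k_out_xval(sim$states, tr, cfg, holdout_fraction = 0.05,
                          seed = 122, max_draws = 40)
  xv2 <- leave_k_out_xval(sim$states, tr, cfg, holdout_fraction = 0.05,
                          seed = 122, max_draws = 40)
  expect_identical(xv1$cells, xv2$cells)

  # beats the majority-class baseline at slow simulated rates
  expect_gt(xv1$summary$agreement, xv1$summary$majority_baseline)
  expect_equal(xv1$summary$n_cells, nrow(xv1$cells))
  expect_true(all(xv1$cells$p_on >= 0 & xv1$cells$p_on <= 1))

  # binned calibration: cells predicted at 0.8-0.9 should agree ~that often
  bin <- dplyr::filter(xv1$cells, pmax(p_on, 1 - p_on) >= 0.8,
                       pmax(p_on, 1 - p_on) <= 0.9)
  if (nrow(bin) >= 20) {
    expect_gte(mean(bin$correct), 0.7 - 3 * sqrt(0.25 / nrow(bin)))
  }

  expect_error(
    leave_k_out_xval(sim$states, tr, cfg, holdout_fraction = 0),
    "holdout_fraction")
})
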