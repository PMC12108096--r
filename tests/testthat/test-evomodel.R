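test_that("relative rate matrix matches the printed form and unit mean flow", {
  Q <- relative_rate_matrix(0.5)
  expect_equal(Q["OFF", "ON"], 1)
  expect_equal(Q["ON", "OFF"], 1)

  Q9 <- relative_rate_matrix(0.9)
  expect_equal(Q9["OFF", "ON"], 5)
  expect_equal(Q9["ON", "OFF"], 5 / 9)
  expect_equal(0.9 * Q9["ON", "OFF"] + 0.1 * Q9["OFF", "ON"], 1)

  set.seed(17)
  for (pi in runif(1000, 1e-4, 1 - 1e-4)) {
    Q <- relative_rate_matrix(pi)
    expect_equal(pi * Q["ON", "OFF"] + (1 - pi) * Q["OFF", "ON"], 1,
                 tolerance = 1e-12)
    # detailed balance
    expect_equal((1 - pi) * Q["OFF", "ON"], pi * Q["ON", "OFF"],
                 tolerance = 1e-12)
    expect_equal(rowSums(Q), c(OFF = 0, ON = 0), tolerance = 1e-12)
  }
  expect_error(relative_rate_matrix(0), "degenerate")
  expect_error(relative_rate_matrix(1), "degenerate")
})

test_that("transition probabilities match the matrix-exponential series oracle", {
  expect_equal(transition_probability(0.3, 1, 0), diag(2), ignore_attr = TRUE)
  Pinf <- transition_probability(0.3, 1, 1e4)
  expect_equal(unname(Pinf[1, ]), c(0.7, 0.3), tolerance = 1e-12)
  expect_equal(unname(Pinf[2, ]), c(0.7, 0.3), tolerance = 1e-12)

  set.seed(23)
  for (i in 1:50) {
    pi <- runif(1, 0.05, 0.95)
    s <- rlnorm(1, -1, 1)
    t <- rlnorm(1, 0, 1)
    P <- transition_probability(pi, s, t)
    expect_equal(P, series_transition(pi, s, t), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(rowSums(P), c(OFF = 1, ON = 1), tolerance = 1e-12)
    # time reversibility: pi_s P_ss' = pi_s' P_s's
    expect_equal((1 - pi) * P["OFF", "ON"], pi * P["ON", "OFF"],
                 tolerance = 1e-12)
  }
  expect_error(transition_probability(0.3, -1, 1), "scale")
  expect_error(transition_probability(0.3, 1, -1), "t must")
})

test_that("discretized gamma categories have equal weights and unit mean", {
  for (xi in c(0.5, 2, 5, 50)) {
    gc <- gamma_categories(xi, k = 6)
    expect_equal(gc$weights, rep(1 / 6, 6))
    expect_equal(sum(gc$weights * gc$rates), 1, tolerance = 1e-8)
    expect_true(all(diff(gc$rates) > 0))
    expect_true(all(gc$rates > 0))
  }
  # vanishing-variance limit
  expect_true(all(abs(gamma_categories(1e6, 6)$rates - 1) < 1e-2))
  # category-rate variance decreases monotonically in xi
  v <- vapply(c(0.5, 1, 2, 5, 20),
              function(xi) var(gamma_categories(xi, 6)$rates), numeric(1))
  expect_true(all(diff(v) < 0))
  expect_error(gamma_categories(0), "xi")
  expect_equal(gamma_categories(3, k = 1)$rates, 1)
})

test_that("pruning likelihood matches hand computation and enumeration oracle", {
  t2 <- read_newick("(A:1,B:1);")
  # all tips missing: likelihood 1
  expect_equal(gene_log_likelihood(t2, c(A = NA, B = NA), 0.4, c(0.3, 0.5)), 0)

  # two tips ON, k = 1: enumerate root states with closed-form P(t)
  pi <- 0.4; r <- c(0.3, 0.5)
  PA <- transition_probability(pi, r[1], 1)
  PB <- transition_probability(pi, r[2], 1)
  hand <- log((1 - pi) * PA["OFF", "ON"] * PB["OFF", "ON"] +
                pi * PA["ON", "ON"] * PB["ON", "ON"])
  expect_equal(gene_log_likelihood(t2, c(A = 1L, B = 1L), pi, r), hand,
               tolerance = 1e-12)

  # 4-tip instances vs exhaustive enumeration over internal-node states
  t4 <- read_newick("((A:1.5,B:1.5):1,(C:0.7,D:0.7):1.8);")
  set.seed(31)
  for (i in 1:20) {
    pi <- runif(1, 0.1, 0.9)
    rates <- rlnorm(6, -0.5, 0.8)
    cats <- gamma_categories(rlnorm(1, log(5), 0.5), k = 2)$rates
    tips <- sample(c(0L, 1L, NA), 4, replace = TRUE)
    names(tips) <- c("A", "B", "C", "D")
    ll <- gene_log_likelihood(t4, tips, pi, rates,
                              structure(list(rates = cats, weights = rep(0.5, 2),
                                             k = 2L), class = "gamma_cats"))
    expect_equal(ll, log(brute_lik(t4, tips, pi, rates, cats)),
                 tolerance = 1e-10)
  }
  expect_error(
    gene_log_likelihood(t4, c(A = 1L, Z = 0L), 0.5, rep(0.1, 6)),
    "not in tree")
})

test_that("log prior matches an independent term-by-term density oracle", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  E <- nrow(branches(tr))
  set.seed(41)
  st <- draw_prior_state(tr)
  oracle <- function(s, mode = "additive") {
    mu <- s$phi + log(2 * s$alpha)
    s2 <- if (mode == "additive") s$theta + 2 * s$beta else s$theta * 2 * s$beta
    Sig <- diag(sqrt(s2)) %*% matrix(c(1, s$correlation, s$correlation, 1), 2) %*%
      diag(sqrt(s2))
    mvn <- sum(vapply(seq_len(nrow(s$log_rates)), function(b) {
      x <- s$log_rates[b, ] - mu
      -log(2 * pi) - 0.5 * determinant(Sig)$modulus[1] -
        0.5 * drop(t(x) %*% solve(Sig) %*% x)
    }, numeric(1)))
    sum(dunif(s$pi, 0, 1, log = TRUE)) +
      sum(dlnorm(s$xi, log(5), 0.587, log = TRUE)) +
      dunif(s$phi, -10, 1, log = TRUE) +
      sum(dbeta(s$alpha, 2, 2, log = TRUE)) +
      (-log(s$theta) - log(log(5) - log(1e-4))) +
      sum(dbeta(s$beta, 10, 10, log = TRUE)) +
      log(1 / 2) +
      mvn
  }
  expect_equal(log_prior(st), oracle(st), tolerance = 1e-10)
  expect_equal(log_prior(st, "multiplicative"), oracle(st, "multiplicative"),
               tolerance = 1e-10)

  # out-of-support values
  bad <- st; bad$pi[1] <- 1.2
  expect_equal(log_prior(bad), -Inf)
  bad <- st; bad$correlation <- 1
  expect_equal(log_prior(bad), -Inf)

  # LKJ eta = 1 in two dimensions: uniform with density 1/2
  s0 <- st; s0$correlation <- 0
  s5 <- st; s5$correlation <- 0.5
  # only the MVN branch term differs between correlations; the LKJ term is flat
  delta_direct <- log_prior(s5) - log_prior(s0)
  delta_oracle <- oracle(s5) - oracle(s0)
  expect_equal(delta_direct, delta_oracle, tolerance = 1e-10)
})

test_that("total log posterior composes prior and likelihood and has the spec symmetries", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  set.seed(43)
  st <- draw_prior_state(tr)
  miss <- missing_states(tr, 5)
  data <- list(AG = miss, testis = miss)
  # no data: posterior equals prior exactly
  expect_equal(total_log_posterior(st, data, tr), log_prior(st))

  obs <- states_from_matrix(matrix(c(1L, 0L, 1L, NA, 1L, 0L), 2, 3), tr)
  d1 <- list(AG = obs, testis = miss)
  lp1 <- total_log_posterior(st, d1, tr)
  # duplicating the gene set doubles the likelihood term
  obs2 <- dplyr::bind_rows(obs, dplyr::mutate(obs, gene = paste0(gene, "b")))
  lp2 <- total_log_posterior(st, list(AG = obs2, testis = miss), tr)
  expect_equal(lp2 - log_prior(st), 2 * (lp1 - log_prior(st)), tolerance = 1e-10)
  # relabeling gene order leaves the value unchanged
  lp3 <- total_log_posterior(st, list(AG = obs[c(2, 1), ], testis = miss), tr)
  expect_equal(lp3, lp1, tolerance = 1e-12)

  # likelihood depends on (phi, alpha) only through mu: compensate and compare
  st2 <- st
  st2$phi <- st$phi + 0.3
  st2$alpha <- pmin(0.999, st$alpha * exp(-0.3))
  # same mu_i = phi + log(2 alpha_i), same branch rates -> same likelihood term
  expect_equal(total_log_posterior(st2, d1, tr) - log_prior(st2),
               lp1 - log_prior(st), tolerance = 1e-10)
})
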