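#' Stationarity-normalized two-state rate matrix
#'
#' The relative rate matrix of the ON/OFF continuous-time Markov chain,
#' parameterized by the stationary ON frequency `pi` and normalized so that
#' the mean transition rate at stationarity is one:
#' `Q[OFF,ON] = 1/(2(1-pi))`, `Q[ON,OFF] = 1/(2 pi)`, diagonals set so rows
#' sum to zero. Rows/columns are ordered (OFF, ON).
#'
#' @param pi Stationary ON frequency in (0, 1).
#' @return A 2x2 matrix with dimnames `c("OFF", "ON")`.
#' @examples
#' relative_rate_matrix(0.5)
#' @export
relative_rate_matrix <- function(pi) {
  if (!(pi > 0 && pi < 1)) abort("pi must be strictly inside (0, 1): matrix is degenerate otherwise")
  q01 <- 1 / (2 * (1 - pi))
  q10 <- 1 / (2 * pi)
  m <- matrix(c(-q01, q10, q01, -q10), nrow = 2,
              dimnames = list(c("OFF", "ON"), c("OFF", "ON")))
  m
}

#' Transition probabilities of the scaled two-state chain
#'
#' Closed-form transition probability matrix over time `t` for the normalized
#' chain scaled by `scale` (the product of a branch rate and a gene-rate
#' category): with activation rate `A = scale/(2(1-pi))` and deactivation
#' `D = scale/(2 pi)`, `P(OFF -> ON) = (A/(A+D)) (1 - exp(-(A+D) t))`, and
#' `A/(A+D) = pi`.
#'
#' @param pi Stationary ON frequency in (0, 1).
#' @param scale Non-negative total rate multiplier.
#' @param t Non-negative elapsed time (MY).
#' @return A 2x2 stochastic matrix, rows/cols ordered (OFF, ON).
#' @export
transition_probability <- function(pi, scale, t) {
  if (!(pi > 0 && pi < 1)) abort("pi must be in (0, 1)")
  if (scale < 0) abort("scale must be >= 0")
  if (t < 0) abort("t must be >= 0")
  e <- exp(-scale * t / (2 * pi * (1 - pi)))
  p01 <- pi * (1 - e)
  p10 <- (1 - pi) * (1 - e)
  matrix(c(1 - p01, p10, p01, 1 - p10), nrow = 2,
         dimnames = list(c("OFF", "ON"), c("OFF", "ON")))
}

#' Discretized-gamma rate categories
#'
#' Among-gene rate variation is modeled by a gamma distribution with mean
#' fixed to 1 (shape = rate = `xi`, so variance `1/xi`), discretized into `k`
#' intervals of equal probability mass; each category's rate is the
#' conditional mean of its interval (computed through the regularized
#' incomplete gamma of shape `xi + 1`), and all mixture weights are `1/k`.
#' The weighted mean of the category rates is exactly 1.
#'
#' @param xi Precision (> 0); larger values mean less rate variation.
#' @param k Number of categories (default 6).
#' @return A `gamma_cats` list with `rates`, `weights`, `xi`, `k`.
#' @examples
#' gamma_categories(5, k = 6)$rates
#' @export
gamma_categories <- function(xi, k = 6) {
  if (xi <= 0) abort("xi must be > 0")
  if (k < 1) abort("k must be >= 1")
  if (k == 1) {
    rates <- 1
  } else {
    bounds <- qgamma(seq_len(k - 1) / k, shape = xi, rate = xi)
    f <- pgamma(c(0, bounds, Inf), shape = xi + 1, rate = xi)
    rates <- k * diff(f)
  }
  structure(list(rates = rates, weights = rep(1 / k, k), xi = xi, k = as.integer(k)),
            class = "gamma_cats")
}
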