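#' Tidy a fitted turnover model
#'
#' One row per scalar model parameter (branch rates excluded; see
#' [branch_rate_summary()]) with posterior mean, median, sd and 95% HPD.
#'
#' @param x A `turnover_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `median`, `std.error`,
#'   `conf.low`, `conf.high`.
#' @method tidy turnover_fit
#' @export
tidy.turnover_fit <- function(x, ...) {
  pars <- setdiff(names(x$trace), c(".chain", "log_posterior", "log_lik"))
  pars <- pars[!grepl("^r_", pars)]
  bind_rows(lapply(pars, function(p) {
    v <- x$trace[[p]]
    h <- hpd_interval(v)
    tibble(term = p, estimate = mean(v), median = median(v),
           std.error = sd(v), conf.low = h[1], conf.high = h[2])
  }))
}

#' One-row summary of a fitted turnover model
#'
#' @param x A `turnover_fit`.
#' @param ... Unused.
#' @return A tibble with sample counts, chain count, mean log posterior and
#'   mean move acceptance.
#' @method glance turnover_fit
#' @export
glance.turnover_fit <- function(x, ...) {
  tibble(n_samples = nrow(x$trace), n_chains = x$config$chains,
         n_genes = nrow(x$data[[1]]),
         mean_log_posterior = mean(x$trace$log_posterior),
         mean_acceptance = mean(x$acceptance$acceptance, na.rm = TRUE))
}

#' Trace plots for a fitted turnover model
#'
#' @param object A `turnover_fit`.
#' @param parameters Parameters to plot (default: the scalar parameters).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot turnover_fit
#' @export
autoplot.turnover_fit <- function(object, parameters = NULL, ...) {
  tr <- object$trace
  if (is.null(parameters)) {
    parameters <- setdiff(names(tr), c(".chain", "log_lik"))
    parameters <- parameters[!grepl("^r_", parameters)]
  }
  long <- tr |>
    mutate(.iter = dplyr::row_number(), .by = ".chain") |>
    tidyr::pivot_longer(all_of(parameters), names_to = "parameter")
  ggplot2::ggplot(long, ggplot2::aes(.data$.iter, .data$value,
                                     colour = factor(.data$.chain))) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "retained sample", y = NULL, colour = "chain")
}

#' Plot a cumulative turnover concentration curve
#'
#' @param object Tibble from [cumulative_turnover_curve()].
#' @param ... Unused.
#' @return A ggplot with the diagonal equal-rates reference.
#' @export
plot_turnover_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$frac_genes, .data$frac_events,
                                       colour = .data$organ)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "black") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "fraction of genes (fastest first)",
                  y = "fraction of turnover events")
}

#' @method autoplot pdmr_result
#' @export
autoplot.pdmr_result <- function(object, null = NULL, ...) {
  p <- ggplot2::ggplot(object$draws, ggplot2::aes(.data$pdmr)) +
    ggplot2::geom_density(ggplot2::aes(colour = .data$organ)) +
    ggplot2::labs(x = "PDMR (%)", y = "density")
  if (!is.null(null)) {
    p <- p + ggplot2::geom_density(data = null,
                                   ggplot2::aes(.data$m_pdmr, colour = .data$organ),
                                   linetype = "dashed")
  }
  p
}

#' @export
print.pdmr_result <- function(x, ...) {
  cat("<pdmr_result>\n")
  print(x$summary)
  invisible(x)
}

#' @export
print.ancestral_root <- function(x, ...) {
  cat("<ancestral_root>\n")
  print(x$summary)
  invisible(x)
}

#' @export
print.xval_result <- function(x, ...) {
  cat("<xval_result>\n")
  print(x$summary)
  invisible(x)
}

#' @export
print.branch_rates <- function(x, ...) {
  cat("<branch_rates> time-weighted organ means:\n")
  print(x$organ_mean)
  invisible(x)
}
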