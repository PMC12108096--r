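#' Read a ternary expression-state matrix from TSV
#'
#' Expects a tab-separated file with gene ids in the first column, one column
#' per species, and cells in `{0, 1, NA}` (0 = OFF, 1 = ON, NA = missing).
#' Any other cell value is rejected with the offending row and column named.
#'
#' @param path Path to a TSV file.
#' @return A wide tibble: `gene` column plus one integer column per species.
#' @export
read_state_matrix <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   na.strings = "NA", colClasses = "character")
  if (ncol(df) < 2) abort("state matrix needs a gene column and >= 1 species column")
  genes <- df[[1]]
  out <- tibble(gene = as.character(genes))
  for (j in seq(2, ncol(df))) {
    v <- df[[j]]
    bad <- !is.na(v) & !v %in% c("0", "1")
    if (any(bad)) {
      i <- which(bad)[1]
      abort(paste0("invalid state '", v[i], "' at row ", i, ", column '",
                   names(df)[j], "': expected 0, 1 or NA"))
    }
    out[[names(df)[j]]] <- as.integer(v)
  }
  out
}

#' Write an expression-state matrix to TSV
#'
#' @param states Wide tibble (`gene` + species columns of 0/1/NA).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_state_matrix <- function(states, path) {
  check_states(states)
  write.table(states, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read a probability-of-expression table from TSV
#'
#' Gene ids in the first column, one column per species (or, for per-library
#' tables, columns `gene`, `species`, `library`, `p`), values in \[0, 1\]
#' with NA preserved.
#'
#' @param path Path to a TSV file.
#' @param organ Optional organ tag stored as an attribute.
#' @return A tibble; wide (gene x species) or long (per-library) depending on
#'   the file layout.
#' @export
read_probability_table <- function(path, organ = NULL) {
  df <- as_tibble(read.delim(path, sep = "\t", header = TRUE,
                             check.names = FALSE, na.strings = "NA"))
  if (all(c("gene", "species", "library", "p") %in% names(df))) {
    check_probs(df$p, "column 'p'")
  } else {
    names(df)[1] <- "gene"
    df$gene <- as.character(df$gene)
    for (j in seq(2, ncol(df))) check_probs(df[[j]], paste0("column '", names(df)[j], "'"))
  }
  if (!is.null(organ)) attr(df, "organ") <- organ
  df
}

#' Write a probability table to TSV
#' @param probs Tibble as returned by [read_probability_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_probability_table <- function(probs, path) {
  write.table(probs, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

check_probs <- function(p, where) {
  bad <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad)) {
    abort(paste0("probability outside [0, 1] (", format(p[which(bad)[1]]),
                 ") in ", where))
  }
  invisible(TRUE)
}

check_states <- function(states) {
  if (!is.data.frame(states) || !"gene" %in% names(states)) {
    abort("expected a tibble with a 'gene' column")
  }
  for (j in setdiff(names(states), "gene")) {
    v <- states[[j]]
    if (!all(is.na(v) | v %in% c(0L, 1L))) {
      abort(paste0("state column '", j, "' contains values outside {0, 1, NA}"))
    }
  }
  invisible(TRUE)
}

#' Write / read a posterior trace as TSV
#'
#' One row per retained sample, one named column per scalar parameter (branch
#' rates as `r_<organ>_<branchIndex>`). Doubles are serialized with 17
#' significant digits so that `read_trace(write_trace(x))` reproduces the
#' values bit-for-bit.
#'
#' @param trace A trace tibble (e.g. `fit$trace`), or a `turnover_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  if (inherits(trace, "turnover_fit")) trace <- trace$trace
  if (!is.data.frame(trace) || nrow(trace) == 0) abort("trace is empty")
  out <- trace
  for (j in names(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @param columns Optional expected column names; a mismatch is a schema error.
#' @export
read_trace <- function(path, columns = NULL) {
  df <- as_tibble(read.delim(path, sep = "\t", header = TRUE,
                             check.names = FALSE))
  if (nrow(df) == 0) abort("trace file has no samples")
  if (!is.null(columns) && !identical(names(df), columns)) {
    abort("trace schema mismatch: column names differ from expected")
  }
  df
}

#' Run configuration
#'
#' Bundles the tunable settings of a full analysis: the discretization
#' cutoff `alpha` (strict-threshold band, `0 < alpha <= 0.5`), the
#' leave-one-library-out range threshold, and the MCMC settings.
#'
#' @param alpha Probability cutoff for discretization (default 0.1).
#' @param range_threshold Leave-one-library-out max-min threshold (default 0.25).
#' @param generations MCMC generations (default 10000).
#' @param thin Sampling interval in generations (default 5).
#' @param burnin_frac Fraction of generations discarded as burn-in (default 0.1).
#' @param seed Integer RNG seed.
#' @param chains Number of independent chains (default 1).
#' @param variance_mode Branch-rate variance composition: `"additive"`
#'   (sigma_i^2 = theta + 2 beta_i, the printed definition) or
#'   `"multiplicative"` (theta * 2 beta_i).
#' @param k Number of discretized-gamma rate categories (default 6).
#' @param paths Optional named list of file paths, carried through untouched.
#' @return A `run_config` list.
#' @export
run_config <- function(alpha = 0.1, range_threshold = 0.25,
                       generations = 10000, thin = 5, burnin_frac = 0.1,
                       seed = 1L, chains = 1L,
                       variance_mode = c("additive", "multiplicative"),
                       k = 6L, paths = list()) {
  variance_mode <- match.arg(variance_mode)
  if (!(alpha > 0 && alpha <= 0.5)) abort("alpha must be in (0, 0.5]")
  if (generations <= 0) abort("generations must be > 0")
  if (thin < 1) abort("thin must be >= 1")
  if (burnin_frac < 0 || burnin_frac >= 1) abort("burnin_frac must be in [0, 1)")
  if (chains < 1) abort("chains must be >= 1")
  if (k < 1) abort("k must be >= 1")
  structure(list(alpha = alpha, range_threshold = range_threshold,
                 generations = as.integer(generations), thin = as.integer(thin),
                 burnin_frac = burnin_frac, seed = as.integer(seed),
                 chains = as.integer(chains), variance_mode = variance_mode,
                 k = as.integer(k), paths = paths),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

#' @rdname run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
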