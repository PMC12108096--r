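#' Discretize probabilities of active expression into ternary states
#'
#' Classifies each gene x species cell as ON when its posterior probability of
#' active expression exceeds `1 - alpha`, OFF when it is below `alpha`, and
#' missing otherwise. The inequalities are strict, so values exactly at either
#' bound (and NA inputs) become missing; at `alpha = 0.5` this collapses to a
#' hard threshold with only `p = 0.5` left missing.
#'
#' @param probs Wide probability tibble (`gene` + species columns in \[0,1\]).
#' @param alpha Cutoff in (0, 0.5].
#' @return Wide state tibble of the same shape with integer 0/1/NA cells.
#' @examples
#' tb <- tibble::tibble(gene = c("g1", "g2"), spA = c(0.97, 0.03))
#' discretize_probabilities(tb, alpha = 0.1)
#' @export
discretize_probabilities <- function(probs, alpha) {
  if (!(alpha > 0 && alpha <= 0.5)) abort("alpha must be in (0, 0.5]")
  out <- tibble(gene = as.character(probs$gene))
  for (j in setdiff(names(probs), "gene")) {
    p <- probs[[j]]
    check_probs(p, paste0("column '", j, "'"))
    s <- rep(NA_integer_, length(p))
    s[!is.na(p) & p > 1 - alpha] <- 1L
    s[!is.na(p) & p < alpha] <- 0L
    out[[j]] <- s
  }
  out
}

#' Leave-one-library-out sensitivity mask
#'
#' Given the leave-one-library-out re-estimates of the probability of active
#' expression (one probability per left-out library), flags every gene x
#' species cell whose max-min range strictly exceeds `range_threshold` as
#' unreliable; such cells are treated as missing downstream. Cells whose
#' range equals the threshold exactly are kept.
#'
#' @param per_library Long tibble with columns `gene`, `species`, `p` (and
#'   optionally `library`); one row per leave-one-out re-estimate.
#' @param range_threshold Strict threshold on max-min (default 0.25).
#' @return Tibble `gene`, `species`, `range`, `mask` (TRUE = set missing).
#' @export
library_sensitivity_filter <- function(per_library, range_threshold = 0.25) {
  need <- c("gene", "species", "p")
  if (!all(need %in% names(per_library))) {
    abort("per_library must have columns gene, species, p")
  }
  check_probs(per_library$p, "column 'p'")
  out <- per_library |>
    group_by(.data$gene, .data$species) |>
    summarise(n_lib = sum(!is.na(.data$p)),
              range = if (sum(!is.na(.data$p)) > 0)
                max(.data$p, na.rm = TRUE) - min(.data$p, na.rm = TRUE)
              else NA_real_,
              .groups = "drop")
  if (any(out$n_lib < 2)) {
    abort("leave-one-library-out filter needs >= 2 libraries per gene x species cell")
  }
  out |>
    mutate(mask = .data$range > range_threshold) |>
    select("gene", "species", "range", "mask")
}

#' Apply a sensitivity mask to a state matrix
#'
#' @param states Wide state tibble.
#' @param mask Output of [library_sensitivity_filter()].
#' @return `states` with masked cells set to NA.
#' @export
apply_sensitivity_mask <- function(states, mask) {
  check_states(states)
  flagged <- mask[mask$mask, , drop = FALSE]
  for (i in seq_len(nrow(flagged))) {
    r <- match(flagged$gene[i], states$gene)
    sp <- flagged$species[i]
    if (!is.na(r) && sp %in% names(states)) states[[sp]][r] <- NA_integer_
  }
  states
}

#' Mixture parameters of the expression-state classifier
#'
#' The replicated-RNA-seq classifier models log-TPM values as a mixture: a
#' spike at zero (probability `rho`), a lognormal "leaky" inactive component
#' (log-mean `mu_inact`), and `K` active lognormal components (log-means
#' `mu_a`, simplex weights `omega_ak`, overall active weight `omega_a`). All
#' lognormal components share log-variance `sigma2`.
#'
#' @param rho Spike probability in \[0,1\].
#' @param omega_a Active-genes weight in \[0,1\].
#' @param omega_ak Active-subcomponent weights (must sum to 1).
#' @param mu_inact Log-mean of the inactive lognormal.
#' @param mu_a Log-means of the active components (same length as `omega_ak`).
#' @param sigma2 Shared log-variance (> 0).
#' @return A `mixture_params` list.
#' @export
mixture_params <- function(rho, omega_a, omega_ak, mu_inact, mu_a, sigma2) {
  if (rho < 0 || rho > 1) abort("rho must be in [0, 1]")
  if (omega_a < 0 || omega_a > 1) abort("omega_a must be in [0, 1]")
  if (any(omega_ak < 0 | omega_ak > 1)) abort("omega_ak must be in [0, 1]")
  if (abs(sum(omega_ak) - 1) > 1e-12) abort("omega_ak must sum to 1")
  if (length(omega_ak) != length(mu_a)) abort("omega_ak and mu_a lengths differ")
  if (sigma2 <= 0) abort("sigma2 must be > 0")
  structure(list(rho = rho, omega_a = omega_a, omega_ak = omega_ak,
                 mu_inact = mu_inact, mu_a = mu_a, sigma2 = sigma2),
            class = "mixture_params")
}

#' Proportion of transcripts from inactive genes
#'
#' The expected fraction of transcript mass produced by inactive (leaky)
#' genes under the classifier's mixture model: the lognormal mean of the
#' leaky inactive component, weighted by its mixture mass, divided by the
#' total expected transcript mass of all TPM-producing components.
#'
#' @param theta A [mixture_params()] object.
#' @return `delta` in \[0, 1\].
#' @export
inactive_transcript_fraction <- function(theta) {
  stopifnot(inherits(theta, "mixture_params"))
  inact <- (1 - theta$rho) * (1 - theta$omega_a) *
    exp(theta$mu_inact + theta$sigma2 / 2)
  act <- theta$omega_a * sum(theta$omega_ak * exp(theta$mu_a + theta$sigma2 / 2))
  denom <- inact + act
  if (denom == 0) abort("delta undefined: no component produces transcripts")
  inact / denom
}

#' Posterior mean of the inactive-transcript fraction
#'
#' Averages [inactive_transcript_fraction()] over posterior draws of the
#' mixture parameters. Draws can be a list of [mixture_params()] or a tibble
#' with one row per draw and columns `rho`, `omega_a`, `mu_inact`, `sigma2`,
#' `omega_ak_1..K`, `mu_ak_1..K` (the TSV convention).
#'
#' @param draws List of `mixture_params` or a draws tibble.
#' @return Mean delta across draws.
#' @export
posterior_mean_delta <- function(draws) {
  if (is.data.frame(draws)) {
    if (nrow(draws) == 0) abort("no draws supplied")
    wk <- sort(grep("^omega_ak_", names(draws), value = TRUE))
    mk <- sort(grep("^mu_ak_", names(draws), value = TRUE))
    draws <- lapply(seq_len(nrow(draws)), function(i) {
      mixture_params(draws$rho[i], draws$omega_a[i],
                     as.numeric(draws[i, wk]), draws$mu_inact[i],
                     as.numeric(draws[i, mk]), draws$sigma2[i])
    })
  }
  if (length(draws) == 0) abort("no draws supplied")
  mean(vapply(draws, inactive_transcript_fraction, numeric(1)))
}

#' Per-group expression summaries
#'
#' For each gene group and species, the expected proportion of actively
#' expressed genes (the mean of the posterior probabilities of expression)
#' and the median expression level of active genes, where "active" means
#' probability of expression > 0.5.
#'
#' @param probs Wide probability tibble.
#' @param labels Tibble `gene`, `group`.
#' @param tpm Optional wide expression-level tibble (same layout as `probs`).
#' @return Tibble `group`, `species`, `n_genes`, `expected_prop_active`,
#'   `median_active_level` (NA when no gene in the group passes 0.5, or no
#'   `tpm` table was given).
#' @export
group_expression_summary <- function(probs, labels, tpm = NULL) {
  if (!all(c("gene", "group") %in% names(labels))) {
    abort("labels must have columns gene, group")
  }
  species <- setdiff(names(probs), "gene")
  res <- list()
  for (g in unique(labels$group)) {
    genes <- labels$gene[labels$group == g]
    idx <- match(genes, probs$gene)
    idx <- idx[!is.na(idx)]
    if (length(idx) == 0) {
      warn(paste0("group '", g, "' matches no genes; returning NA"))
      res[[g]] <- tibble(group = g, species = species, n_genes = 0L,
                         expected_prop_active = NA_real_,
                         median_active_level = NA_real_)
      next
    }
    res[[g]] <- bind_rows(lapply(species, function(sp) {
      p <- probs[[sp]][idx]
      lev <- NA_real_
      if (!is.null(tpm) && sp %in% names(tpm)) {
        tl <- tpm[[sp]][match(probs$gene[idx], tpm$gene)]
        act <- !is.na(p) & p > 0.5
        lev <- if (any(act)) median(tl[act], na.rm = TRUE) else NA_real_
      }
      tibble(group = g, species = sp, n_genes = length(idx),
             expected_prop_active = mean(p, na.rm = TRUE),
             median_active_level = lev)
    }))
  }
  bind_rows(res)
}
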