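#' Randomly select allele frequencies
#'
#' Draws allele frequencies uniformly between 0.1 and 0.9, the range used
#' when the user does not provide frequencies for a genetic factor.
#'
#' @param count Number of frequencies to draw.
#' @return Numeric vector in `[0.1, 0.9]`. Uses the current RNG state.
#' @export
sample_allele_freqs <- function(count) {
  stopifnot(is.numeric(count), length(count) == 1L, count >= 1)
  stats::runif(count, 0.1, 0.9)
}

#' Hardy-Weinberg genotype frequencies
#'
#' Converts an allele frequency `p` into the genotype-frequency triple
#' `(p^2, 2p(1-p), (1-p)^2)` for (AA, Aa, aa) under random mating.
#'
#' @param p Allele frequency of the reference allele, in (0, 1).
#' @return Probability triple summing to 1.
#' @examples
#' hwe_genotype_freqs(0.5)  # 0.25 0.50 0.25
#' @export
hwe_genotype_freqs <- function(p) {
  stopifnot(is.numeric(p), length(p) == 1L, is.finite(p))
  if (p <= 0 || p >= 1) stop("`p` must lie strictly in (0, 1)", call. = FALSE)
  c(p^2, 2 * p * (1 - p), (1 - p)^2)
}

check_freq_triple <- function(fr) {
  if (!is.numeric(fr) || length(fr) != 3L || any(!is.finite(fr)) ||
      any(fr < 0) || abs(sum(fr) - 1) > 1e-9) {
    stop("genotype frequencies must be a nonnegative triple summing to 1",
         call. = FALSE)
  }
  fr
}

#' Assign genotypes to individuals
#'
#' Monte Carlo assignment: each genetic factor's column is drawn i.i.d.
#' categorical from its genotype-frequency triple; columns are independent.
#'
#' @param n Number of individuals.
#' @param freqs A probability triple or a list of triples (one per gene).
#' @return Integer matrix `n x G` of genotype indices in `{1, 2, 3}`.
#' @export
assign_genotypes <- function(n, freqs) {
  stopifnot(is.numeric(n), n >= 1)
  if (is.numeric(freqs)) freqs <- list(freqs)
  g <- vapply(freqs, function(fr) {
    fr <- check_freq_triple(fr)
    sample.int(3L, n, replace = TRUE, prob = fr)
  }, integer(n))
  matrix(as.integer(g), nrow = n,
         dimnames = list(NULL, paste0("G", seq_along(freqs))))
}

#' Assign environmental exposures to individuals
#'
#' Monte Carlo assignment: each environmental factor's column is drawn
#' i.i.d. from its exposure distribution; columns are independent
#' (environmental variables are assumed independent).
#'
#' @param n Number of individuals.
#' @param dists A [`gxe_env`][environment-distributions] or a list of them.
#' @return Numeric matrix `n x E` of exposure levels.
#' @export
assign_exposures <- function(n, dists) {
  stopifnot(is.numeric(n), n >= 1)
  if (is_gxe_env(dists)) dists <- list(dists)
  x <- vapply(dists, function(d) env_sample(d, n), numeric(n))
  matrix(x, nrow = n, dimnames = list(NULL, paste0("E", seq_along(dists))))
}

#' Compute individual disease risks
#'
#' Evaluates the penetrance model on the causal columns only: with one-gene
#' coefficients, `risk = logistic(alpha[g] + beta[g] * x)` for the causal
#' genotype `g` and causal exposure `x`; with a general coefficient table,
#' the entry keyed by the causal genotype tuple supplies the intercept and
#' the slopes of the causal exposures. Noise factors never enter the risk.
#'
#' @param genotypes Integer matrix of genotype indices (`n x G`).
#' @param exposures Numeric matrix of exposures (`n x E`).
#' @param coeffs An [mlm_coefficients()] or [coef_table()] object.
#' @param causal_gene,causal_env Column index (or indices, for a table) of
#'   the causal factors.
#' @return Numeric vector of risks in `[0, 1]`.
#' @export
assign_risk <- function(genotypes, exposures, coeffs,
                        causal_gene = 1L, causal_env = 1L) {
  genotypes <- as.matrix(genotypes); exposures <- as.matrix(exposures)
  stopifnot(nrow(genotypes) == nrow(exposures))
  if (any(causal_gene < 1L) || any(causal_gene > ncol(genotypes))) {
    stop("`causal_gene` out of range", call. = FALSE)
  }
  if (any(causal_env < 1L) || any(causal_env > ncol(exposures))) {
    stop("`causal_env` out of range", call. = FALSE)
  }
  if (inherits(coeffs, "mlm_coefficients")) {
    stopifnot(length(causal_gene) == 1L, length(causal_env) == 1L)
    g <- check_genotype_index(genotypes[, causal_gene])
    x <- exposures[, causal_env]
    logistic(coeffs$alpha[g] + coeffs$beta[g] * x)
  } else if (inherits(coeffs, "mlm_coef_table")) {
    if (length(causal_gene) != coeffs$n_genes ||
        length(causal_env) != coeffs$n_envs) {
      stop("causal factor counts do not match the coefficient-table dimensions",
           call. = FALSE)
    }
    gm <- genotypes[, causal_gene, drop = FALSE]
    keys <- apply(gm, 1L, paste, collapse = ",")
    al <- vapply(coeffs$entries, `[[`, numeric(1), "alpha")
    bm <- matrix(unlist(lapply(coeffs$entries, function(e) as.numeric(e$beta))),
                 ncol = coeffs$n_envs, byrow = TRUE,
                 dimnames = list(names(coeffs$entries), NULL))
    xm <- exposures[, causal_env, drop = FALSE]
    lin <- al[keys] + rowSums(xm * bm[keys, , drop = FALSE])
    unname(logistic(lin))
  } else {
    stop("`coeffs` must be mlm_coefficients or an mlm_coef_table", call. = FALSE)
  }
}

#' Assign disease status from risks
#'
#' Monte Carlo status assignment: a uniform [0, 1] number is drawn per
#' individual and the individual is affected (status 1) if the draw is
#' strictly less than the disease risk, not affected (0) otherwise.
#'
#' @param risk Numeric vector of risks in `[0, 1]`.
#' @return Integer vector of 0/1 statuses. Uses the current RNG state.
#' @export
assign_status <- function(risk) {
  if (!is.numeric(risk) || any(!is.finite(risk)) ||
      any(risk < 0) || any(risk > 1)) {
    stop("`risk` must contain probabilities in [0, 1]", call. = FALSE)
  }
  as.integer(stats::runif(length(risk)) < risk)
}

# Expand one root seed into named sub-streams so that, e.g., adding an
# environmental factor cannot perturb the genotype draws.
derive_stream_seeds <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L, seed == floor(seed))
  set.seed(as.integer(seed))
  stats::setNames(sample.int(.Machine$integer.max - 1L, 3L),
                  c("genotypes", "exposures", "status"))
}

#' Simulate a case-control population
#'
#' Runs the full generation pipeline: solve the model coefficients from the
#' epidemiological inputs (or take the user's coefficient table in
#' `"CUSTOM"` mode), assign genotypes and exposures by Monte Carlo, compute
#' each individual's disease risk from the causal factors, and draw disease
#' status. Infeasible parameter combinations fail before any sampling.
#'
#' The root seed is expanded into independent named sub-streams for the
#' genotype, exposure and status draws, so identical `(spec, seed)` pairs
#' give identical datasets.
#'
#' @param spec A [population_spec()].
#' @param seed Integer root seed.
#' @return An object of class `gxe_dataset`: genotype and exposure matrices,
#'   risk and status vectors, plus the spec, seed and solver provenance.
#' @examples
#' spec <- population_spec(500, hwe_genotype_freqs(0.4), env_uniform(0, 4),
#'                         m = 0.1, model = "AM", rr31 = 3, w = 0.5,
#'                         env_or = 1.5)
#' sim <- simulate_population(spec, seed = 1)
#' mean(sim$status)
#' @export
simulate_population <- function(spec, seed) {
  stopifnot(inherits(spec, "population_spec"))
  solution <- if (spec$model == "CUSTOM") NULL else solve_coefficients(spec)
  coeffs <- if (spec$model == "CUSTOM") spec$coef_table else solution$coefficients

  seeds <- derive_stream_seeds(seed)
  set.seed(seeds[["genotypes"]])
  genotypes <- assign_genotypes(spec$n, spec$genotype_freqs)
  set.seed(seeds[["exposures"]])
  exposures <- assign_exposures(spec$n, spec$env)
  risk <- assign_risk(genotypes, exposures, coeffs,
                      causal_gene = spec$causal_gene,
                      causal_env = spec$causal_env)
  set.seed(seeds[["status"]])
  status <- assign_status(risk)

  structure(list(genotypes = genotypes, exposures = exposures, risk = risk,
                 status = status, spec = spec, seed = as.integer(seed),
                 solution = solution),
            class = "gxe_dataset")
}

#' @export
print.gxe_dataset <- function(x, ...) {
  cat(sprintf("<simulated case-control dataset: n = %d (%d affected), %d gene(s), %d environment(s)>\n",
              length(x$status), sum(x$status), ncol(x$genotypes),
              ncol(x$exposures)))
  cat(sprintf("  model = %s, seed = %d\n", x$spec$model, x$seed))
  invisible(x)
}

#' Coerce a simulated dataset to a data frame
#'
#' Genotypes are serialized as risk-allele counts 0/1/2 (genotype index
#' minus one); exposures are raw values.
#'
#' @param x A `gxe_dataset`.
#' @param row.names,optional Ignored; present for the generic.
#' @param include_risk Include the latent `risk` column.
#' @param ... Ignored.
#' @return A data frame with columns `id`, `G*`, `E*`, optionally `risk`,
#'   and `status`.
#' @export
as.data.frame.gxe_dataset <- function(x, row.names = NULL, optional = FALSE,
                                      include_risk = TRUE, ...) {
  df <- data.frame(id = seq_along(x$status),
                   x$genotypes - 1L,
                   x$exposures,
                   check.names = FALSE)
  if (include_risk) df$risk <- x$risk
  df$status <- x$status
  df
}

#' Subsample a fixed cases-to-controls design
#'
#' Convenience utility, not part of the generative model: the simulator
#' assigns status by independent Bernoulli draws, so the number of affected
#' individuals is binomial rather than fixed. This helper draws (without
#' replacement) a requested number of cases and controls from a simulated
#' dataset, e.g. to build a balanced case-control study.
#'
#' @param dataset A `gxe_dataset`.
#' @param n_cases,n_controls Numbers of affected / unaffected individuals to
#'   retain; must not exceed what the dataset contains.
#' @return A `gxe_dataset` restricted to the sampled rows (in original
#'   order). Uses the current RNG state.
#' @export
sample_case_control <- function(dataset, n_cases, n_controls) {
  stopifnot(inherits(dataset, "gxe_dataset"))
  cases <- which(dataset$status == 1L)
  controls <- which(dataset$status == 0L)
  if (n_cases > length(cases) || n_controls > length(controls)) {
    stop(sprintf("dataset holds %d cases and %d controls; requested %d and %d",
                 length(cases), length(controls), n_cases, n_controls),
         call. = FALSE)
  }
  keep <- sort(c(sample(cases, n_cases), sample(controls, n_controls)))
  out <- dataset
  out$genotypes <- dataset$genotypes[keep, , drop = FALSE]
  out$exposures <- dataset$exposures[keep, , drop = FALSE]
  out$risk <- dataset$risk[keep]
  out$status <- dataset$status[keep]
  out
}
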