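#' Maximum-likelihood logistic fit of status on one covariate
#'
#' Minimal Newton-Raphson fit of `status ~ intercept + x`, used by the
#' validation report to recover per-genotype exposure slopes. Iterates until
#' the coefficient update satisfies `max(|delta|) < 1e-8` (at most
#' `max_iter` iterations); standard errors come from the inverse Fisher
#' information at the optimum. Degenerate strata (no observations, constant
#' outcome, or a separating covariate) are reported as not converged with
#' `NA` coefficients.
#'
#' @param x Numeric covariate vector.
#' @param y 0/1 response vector.
#' @param max_iter Iteration cap.
#' @return List with `coef` (intercept, slope), `se`, `converged`,
#'   `iterations`, `n`.
#' @export
logit_fit <- function(x, y, max_iter = 50L) {
  stopifnot(length(x) == length(y))
  bad <- list(coef = c(NA_real_, NA_real_), se = c(NA_real_, NA_real_),
              converged = FALSE, iterations = 0L, n = length(y))
  if (length(y) == 0L || length(unique(y)) < 2L || stats::var(x) == 0) {
    return(bad)
  }
  X <- cbind(1, x)
  b <- c(stats::qlogis(mean(y)), 0)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% b)
    mu <- stats::plogis(eta)
    wt <- mu * (1 - mu)
    info <- crossprod(X, X * wt)
    score <- crossprod(X, y - mu)
    delta <- tryCatch(drop(solve(info, score)), error = function(e) NULL)
    if (is.null(delta) || any(!is.finite(delta))) return(bad)
    b <- b + delta
    if (max(abs(delta)) < 1e-8) {
      se <- sqrt(diag(solve(crossprod(X, X * (stats::plogis(drop(X %*% b)) *
                                              (1 - stats::plogis(drop(X %*% b))))))))
      return(list(coef = unname(b), se = unname(se), converged = TRUE,
                  iterations = it, n = length(y)))
    }
  }
  bad
}

#' Validation summary of a simulated dataset
#'
#' Recomputes the headline epidemiological measures from a simulated sample
#' and compares them with what the specification requested: empirical
#' prevalence, affected fraction per causal genotype (the empirical total
#' risks), the heterozygote and homozygote risk ratios, and the
#' maximum-likelihood logistic slope of status on the causal exposure within
#' each genotype stratum. Discrepancies are expressed as z-scores in
#' standard-error units (binomial standard errors for the fractions, Wald
#' standard errors for the slopes).
#'
#' @param dataset A `gxe_dataset` from [simulate_population()].
#' @param spec The generating [population_spec()]; defaults to the one
#'   stored in the dataset. If the dataset carries solver provenance, the
#'   solved coefficients provide the slope targets.
#' @return An object of class `gxe_summary`.
#' @export
summarize_dataset <- function(dataset, spec = dataset$spec) {
  stopifnot(inherits(dataset, "gxe_dataset"))
  status <- dataset$status
  n <- length(status)
  g <- dataset$genotypes[, spec$causal_gene]
  x <- dataset$exposures[, spec$causal_env]

  prevalence <- mean(status)
  strata <- lapply(1:3, function(i) which(g == i))
  frac <- vapply(strata, function(idx) {
    if (length(idx) == 0L) NA_real_ else mean(status[idx])
  }, numeric(1))
  frac_se <- vapply(1:3, function(i) {
    ni <- length(strata[[i]])
    if (ni == 0L || is.na(frac[i])) NA_real_
    else sqrt(frac[i] * (1 - frac[i]) / ni)
  }, numeric(1))

  rr21 <- if (!is.na(frac[1]) && frac[1] > 0) frac[2] / frac[1] else NA_real_
  rr31 <- if (!is.na(frac[1]) && frac[1] > 0) frac[3] / frac[1] else NA_real_

  fits <- lapply(1:3, function(i) logit_fit(x[strata[[i]]], status[strata[[i]]]))
  slope <- vapply(fits, function(f) f$coef[2], numeric(1))
  slope_se <- vapply(fits, function(f) f$se[2], numeric(1))

  sol <- dataset$solution
  target_tr <- if (!is.null(sol)) sol$achieved_tr else rep(NA_real_, 3)
  target_beta <- if (!is.null(sol)) sol$coefficients$beta else rep(NA_real_, 3)

  z_prev <- (prevalence - spec$m) / sqrt(spec$m * (1 - spec$m) / n)
  z_tr <- (frac - target_tr) / frac_se
  z_slope <- (slope - target_beta) / slope_se

  structure(list(
    n = n,
    empirical_prevalence = prevalence,
    per_genotype_risk = frac,
    per_genotype_risk_se = frac_se,
    stratum_sizes = lengths(strata),
    empirical_rr21 = rr21,
    empirical_rr31 = rr31,
    per_genotype_slope = slope,
    per_genotype_slope_se = slope_se,
    slope_converged = vapply(fits, `[[`, logical(1), "converged"),
    spec_targets = list(m = spec$m, tr = target_tr, beta = target_beta,
                        rr21 = if (spec$model == "CUSTOM") NA_real_
                               else heterozygote_rr(spec$rr31, spec$w),
                        rr31 = if (spec$model == "CUSTOM") NA_real_
                               else spec$rr31),
    z_scores = list(prevalence = z_prev, per_genotype_risk = z_tr,
                    per_genotype_slope = z_slope)),
    class = "gxe_summary")
}

#' @export
print.gxe_summary <- function(x, ...) {
  cat(sprintf("<validation summary: n = %d>\n", x$n))
  cat(sprintf("  prevalence: %.4f (target %.4f, z = %+.2f)\n",
              x$empirical_prevalence, x$spec_targets$m, x$z_scores$prevalence))
  cat("  affected fraction by causal genotype:\n")
  for (i in 1:3) {
    cat(sprintf("    genotype %d: %.4f (n = %d)\n", i, x$per_genotype_risk[i],
                x$stratum_sizes[i]))
  }
  cat(sprintf("  empirical RR21 = %.3f, RR31 = %.3f\n",
              x$empirical_rr21, x$empirical_rr31))
  cat(sprintf("  per-genotype exposure slope: %s\n",
              paste(signif(x$per_genotype_slope, 4), collapse = ", ")))
  invisible(x)
}

#' Monte Carlo estimate of the total (marginal) risk
#'
#' Independent sampling-based check of [total_risk()]: averages
#' `logistic(alpha + beta * x)` over `n` draws from the exposure
#' distribution and reports the Monte Carlo standard error.
#'
#' @param alpha,beta Scalar coefficients.
#' @param env A [`gxe_env`][environment-distributions] object.
#' @param n Number of draws.
#' @return List with `estimate` and `se`. Uses the current RNG state.
#' @export
mc_total_risk <- function(alpha, beta, env, n) {
  stopifnot(n >= 1)
  r <- logistic(alpha + beta * env_sample(env, n))
  list(estimate = mean(r), se = stats::sd(r) / sqrt(n))
}
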