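#' Target total risks from epidemiological inputs
#'
#' The overall disease frequency decomposes over genotypes as
#' `m = sum_i P_i * TR_i`. Writing the heterozygote and high-risk homozygote
#' risks relative to the reference (`TR_2 = RR21 * TR_1`,
#' `TR_3 = RR31 * TR_1`, with `RR21 = 1 + W * (RR31 - 1)`) and solving for
#' the reference risk gives
#' `TR_1 = m / (P_1 + P_2 * RR21 + P_3 * RR31)`.
#' The returned triple conserves `m` exactly.
#'
#' @param m Overall disease frequency in (0, 1).
#' @param genotype_freqs Probability triple `(P_1, P_2, P_3)`.
#' @param rr31 Relative risk of the high-risk homozygote, `>= 1`.
#' @param w Inheritance weight in `[0, 1]`.
#' @return Numeric triple `(TR_1, TR_2, TR_3)`.
#' @examples
#' target_total_risks(0.1, c(0.25, 0.5, 0.25), rr31 = 3, w = 1)
#' @export
target_total_risks <- function(m, genotype_freqs, rr31, w) {
  stopifnot(is.numeric(m), length(m) == 1L, m > 0, m < 1,
            is.numeric(genotype_freqs), length(genotype_freqs) == 3L,
            all(genotype_freqs >= 0),
            abs(sum(genotype_freqs) - 1) <= 1e-9)
  rr21 <- heterozygote_rr(rr31, w)
  tr1 <- m / sum(genotype_freqs * c(1, rr21, rr31))
  tr <- tr1 * c(1, rr21, rr31)
  if (any(tr >= 1)) {
    i <- which(tr >= 1)[1]
    stop(sprintf(paste0("infeasible parameters: TR_%d = %.4f >= 1; the disease ",
                        "frequency m = %g is too large for the requested relative risks"),
                 i, tr[i], m), call. = FALSE)
  }
  tr
}

# Solve total_risk(alpha, beta, env) = target for alpha. The marginal risk
# is strictly increasing in alpha, so a bracketed root on [-50, 50] log-odds
# always applies; a point-mass environment admits the closed form
# alpha = logit(target) - beta * x0.
root_alpha <- function(beta, target, env, bracket = c(-50, 50)) {
  if (beta == 0) return(stats::qlogis(target))
  if (env_is_point_mass(env)) {
    return(stats::qlogis(target) - beta * env$values)
  }
  f <- function(a) total_risk(a, beta, env) - target
  lo <- f(bracket[1]); hi <- f(bracket[2])
  if (lo > 0 || hi < 0) {
    stop(sprintf(paste0("no intercept in [%g, %g] log-odds reaches total risk %.4g ",
                        "with slope %.4g under this exposure distribution"),
                 bracket[1], bracket[2], target, beta), call. = FALSE)
  }
  stats::uniroot(f, bracket, f.lower = lo, f.upper = hi,
                 tol = 1e-13, maxiter = 2000L)$root
}

# Solve total_risk(alpha, beta, env) = target for beta. Requires nonnegative
# exposure support so the marginal risk is monotone (nondecreasing) in beta.
root_beta <- function(alpha, target, env, bracket = c(-60, 60)) {
  if (env_support_min(env) < 0) {
    stop(paste0("deriving genotype-specific slopes requires a nonnegative exposure ",
                "support (the marginal risk must be monotone in the slope); ",
                "shift the exposure scale so its minimum is >= 0"),
         call. = FALSE)
  }
  if (env_is_point_mass(env)) {
    x0 <- env$values
    if (x0 == 0) {
      stop("a point-mass exposure at 0 cannot produce genotype-specific total risks",
           call. = FALSE)
    }
    return((stats::qlogis(target) - alpha) / x0)
  }
  f <- function(b) total_risk(alpha, b, env) - target
  lo <- f(bracket[1]); hi <- f(bracket[2])
  if (lo > 0 || hi < 0) {
    stop(sprintf(paste0("no slope in [%g, %g] reaches total risk %.4g with ",
                        "intercept %.4g under this exposure distribution"),
                 bracket[1], bracket[2], target, alpha), call. = FALSE)
  }
  stats::uniroot(f, bracket, f.lower = lo, f.upper = hi,
                 tol = 1e-13, maxiter = 2000L)$root
}

causal_env_of <- function(spec) spec$env[[spec$causal_env]]
causal_freqs_of <- function(spec) spec$genotype_freqs[[spec$causal_gene]]

make_solution <- function(spec, alpha, beta, target_tr) {
  coeffs <- mlm_coefficients(alpha, beta)
  env <- causal_env_of(spec)
  achieved <- vapply(1:3, function(i) total_risk(alpha[i], beta[i], env),
                     numeric(1))
  res <- structure(
    list(model = spec$model,
         coefficients = coeffs,
         target_tr = target_tr,
         achieved_tr = achieved,
         max_residual = max(abs(achieved - target_tr)),
         rr21 = heterozygote_rr(spec$rr31, spec$w),
         rr31 = spec$rr31),
    class = "gxe_solution")
  v <- validate_constraints(coeffs, spec$model)
  if (!v$valid) {
    stop(paste0("solved coefficients violate the interaction-model constraints: ",
                paste(v$violations, collapse = "; ")), call. = FALSE)
  }
  res
}

#' @export
print.gxe_solution <- function(x, ...) {
  cat(sprintf("<coefficient solution: model %s>\n", x$model))
  print(x$coefficients)
  cat(sprintf("  target TR:   %s\n", paste(signif(x$target_tr, 6), collapse = ", ")))
  cat(sprintf("  achieved TR: %s\n", paste(signif(x$achieved_tr, 6), collapse = ", ")))
  cat(sprintf("  max residual: %.3g\n", x$max_residual))
  invisible(x)
}

#' Solve the genetic-only model
#'
#' Under the genetic model (GM) the environment has no effect: all slopes
#' are zero and each intercept is the logit of its genotype's target total
#' risk, in closed form.
#'
#' @param spec A [population_spec()] with `model = "GM"`.
#' @return A `gxe_solution` (coefficients, target and achieved total risks,
#'   residual).
#' @export
solve_gm <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  tr <- target_total_risks(spec$m, causal_freqs_of(spec), spec$rr31, spec$w)
  make_solution(spec, alpha = stats::qlogis(tr), beta = rep(0, 3),
                target_tr = tr)
}

#' Solve the environmental-only model
#'
#' Under the environmental model (EM) all genotypes share one risk curve:
#' the slope is `log(env_or)` (nonzero by constraint) and the shared
#' intercept is found by monotone root-finding so that the marginal risk
#' equals the disease frequency `m`. Because genetics must not alter risk,
#' specifications with `rr31 != 1` are rejected rather than silently ignored.
#'
#' @param spec A [population_spec()] with `model = "EM"`.
#' @return A `gxe_solution`.
#' @export
solve_em <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  if (spec$rr31 != 1) {
    stop("the environmental-only model forces equal risks across genotypes; set rr31 = 1",
         call. = FALSE)
  }
  if (spec$env_or == 1) {
    stop("the environmental-only model requires a nonzero exposure effect; env_or must differ from 1",
         call. = FALSE)
  }
  tr <- target_total_risks(spec$m, causal_freqs_of(spec), 1, spec$w)
  beta <- log(spec$env_or)
  alpha <- root_alpha(beta, spec$m, causal_env_of(spec))
  make_solution(spec, alpha = rep(alpha, 3), beta = rep(beta, 3),
                target_tr = tr)
}

#' Solve the additive model
#'
#' Under the additive model (AM) the exposure has the same effect in every
#' genotype (shared slope `log(env_or)`, nonzero) while each genotype has
#' its own basal risk: each intercept is found by independent monotone
#' root-finding so the genotype's marginal risk matches its target total
#' risk. Intercept ordering follows the total-risk ordering.
#'
#' @param spec A [population_spec()] with `model = "AM"`.
#' @return A `gxe_solution`.
#' @export
solve_am <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  if (spec$env_or == 1) {
    stop("the additive model requires a nonzero exposure effect; env_or must differ from 1",
         call. = FALSE)
  }
  tr <- target_total_risks(spec$m, causal_freqs_of(spec), spec$rr31, spec$w)
  beta <- log(spec$env_or)
  env <- causal_env_of(spec)
  alpha <- vapply(tr, function(t) root_alpha(beta, t, env), numeric(1))
  make_solution(spec, alpha = alpha, beta = rep(beta, 3), target_tr = tr)
}

#' Solve the gene-modulated (interaction) model
#'
#' Under the interaction model (GEM) genotypes share one basal risk but
#' differ in their susceptibility to the exposure
#' (`alpha_1 = alpha_2 = alpha_3`, `beta_1 <= beta_2 <= beta_3`). The user's
#' odds ratio anchors the reference-homozygote slope,
#' `beta_1 = log(env_or)`; the shared intercept is then solved so the
#' reference marginal risk matches `TR_1`, and the remaining slopes are
#' solved so the other genotypes match `TR_2` and `TR_3`. This requires a
#' nonnegative exposure support (the marginal risk must be monotone in the
#' slope); the slope ordering is verified after solving.
#'
#' @param spec A [population_spec()] with `model = "GEM"`.
#' @return A `gxe_solution`.
#' @export
solve_gem <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  tr <- target_total_risks(spec$m, causal_freqs_of(spec), spec$rr31, spec$w)
  env <- causal_env_of(spec)
  if (env_support_min(env) < 0) {
    stop(paste0("the gene-modulated model requires a nonnegative exposure support ",
                "(the marginal risk must be monotone in the slope); shift the ",
                "exposure scale so its minimum is >= 0"), call. = FALSE)
  }
  beta <- numeric(3)
  beta[1] <- log(spec$env_or)
  alpha <- root_alpha(beta[1], tr[1], env)
  for (i in 2:3) {
    beta[i] <- if (abs(tr[i] - tr[1]) < 1e-14) beta[1]
               else root_beta(alpha, tr[i], env)
  }
  make_solution(spec, alpha = rep(alpha, 3), beta = beta, target_tr = tr)
}

#' Solve model coefficients from epidemiological inputs
#'
#' Dispatches to the model-specific solver (GM, EM, GEM or AM), turning the
#' population description — genotype frequencies, disease frequency `m`,
#' relative risk `rr31`, inheritance weight `w`, environmental odds ratio —
#' into the three `(alpha, beta)` pairs of the one-gene multi-logistic
#' model, and verifies the interaction-model constraints on the result.
#'
#' @param spec A [population_spec()] with a non-`"CUSTOM"` model.
#' @return A `gxe_solution` containing an [mlm_coefficients()] object with
#'   exactly three `(alpha, beta)` pairs, the target and achieved total
#'   risks, and the maximum residual.
#' @examples
#' spec <- population_spec(1000, hwe_genotype_freqs(0.5),
#'                         env_discrete(c(0, 1), c(0.5, 0.5)),
#'                         m = 0.1, model = "AM", rr31 = 3, w = 1, env_or = 2)
#' solve_coefficients(spec)
#' @export
solve_coefficients <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  switch(spec$model,
    GM = solve_gm(spec),
    EM = solve_em(spec),
    GEM = solve_gem(spec),
    AM = solve_am(spec),
    CUSTOM = stop("model \"CUSTOM\" takes coefficients directly; supply a coef_table() instead of solving",
                  call. = FALSE))
}

#' Check interaction-model constraints on coefficients
#'
#' Each interaction model is a pattern of equalities and inequalities over
#' the per-genotype coefficients: GM needs `alpha` nondecreasing and all
#' `beta` zero; EM needs shared `alpha` and one shared nonzero `beta`; GEM
#' needs shared `alpha` and nondecreasing `beta`; AM needs nondecreasing
#' `alpha` and one shared nonzero `beta`. Equalities are checked with an
#' absolute tolerance (default 1e-9). All violations are reported, not just
#' the first.
#'
#' @param coeffs An [mlm_coefficients()] object.
#' @param model One of `"GM"`, `"EM"`, `"GEM"`, `"AM"`.
#' @param tol Absolute tolerance on equalities (and slack on inequalities).
#' @return A list with `valid` (logical) and `violations` (character).
#' @examples
#' validate_constraints(mlm_coefficients(c(1, 1, 1), c(0.2, 0.5, 0.9)), "GEM")
#' @export
validate_constraints <- function(coeffs, model, tol = 1e-9) {
  stopifnot(inherits(coeffs, "mlm_coefficients"))
  model <- match.arg(model, c("GM", "EM", "GEM", "AM"))
  a <- coeffs$alpha; b <- coeffs$beta
  viol <- character(0)
  eq <- function(x) max(x) - min(x) <= tol
  nondecr <- function(x) all(diff(x) >= -tol)
  if (model %in% c("GM", "AM") && !nondecr(a)) {
    viol <- c(viol, "alpha_1 <= alpha_2 <= alpha_3 violated")
  }
  if (model %in% c("EM", "GEM") && !eq(a)) {
    viol <- c(viol, "alpha_1 = alpha_2 = alpha_3 violated")
  }
  if (model == "GM" && any(abs(b) > tol)) {
    viol <- c(viol, "beta_1 = beta_2 = beta_3 = 0 violated")
  }
  if (model %in% c("EM", "AM")) {
    if (!eq(b)) viol <- c(viol, "beta_1 = beta_2 = beta_3 violated")
    if (all(abs(b) <= tol)) viol <- c(viol, "shared beta must be nonzero")
  }
  if (model == "GEM" && !nondecr(b)) {
    viol <- c(viol, "beta_1 <= beta_2 <= beta_3 violated")
  }
  list(valid = length(viol) == 0L, violations = viol)
}
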