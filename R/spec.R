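#' Specification of a simulated population
#'
#' Bundles the parameters a case-control simulation needs: sample size,
#' genetic factors (genotype frequencies), environmental factors (exposure
#' distributions), the overall disease frequency `m`, the interaction model,
#' and the epidemiological effect measures the coefficient solver must
#' reproduce (`rr31`, inheritance weight `w`, environmental odds ratio).
#'
#' One gene and one environmental factor (the causal pair) drive the disease
#' risk; any additional factors act as noise background and never enter the
#' risk function.
#'
#' @param n Number of individuals.
#' @param genotype_freqs A probability triple `(P(AA), P(Aa), P(aa))`, or a
#'   list of triples (one per genetic factor). Each triple must sum to 1
#'   (tolerance 1e-9). Use [hwe_genotype_freqs()] to derive a triple from an
#'   allele frequency.
#' @param env A [`gxe_env`][environment-distributions] object or a list of
#'   them (one per environmental factor).
#' @param m Overall disease frequency (expected prevalence), in (0, 1).
#' @param model Interaction model: `"GM"` (genetic only), `"EM"`
#'   (environmental only), `"GEM"` (gene-modulated response to the
#'   environment), `"AM"` (additive), or `"CUSTOM"` (user-supplied
#'   coefficient table).
#' @param rr31 Relative risk of the high-risk homozygote versus the
#'   reference homozygote, `>= 1`.
#' @param w Inheritance weight in `[0, 1]`: 0 recessive, 1 dominant,
#'   in between co-dominant.
#' @param env_or Odds ratio of disease per one-unit increase of the causal
#'   exposure, `> 0`; its logarithm anchors the exposure slope.
#' @param causal_gene,causal_env Index (or, for `"CUSTOM"`, indices) of the
#'   factor(s) that drive the risk. Remaining factors are noise.
#' @param coef_table For `model = "CUSTOM"`, an [coef_table()] whose
#'   dimensions match the causal factor counts.
#' @return An object of class `population_spec`.
#' @examples
#' population_spec(
#'   n = 2000, genotype_freqs = hwe_genotype_freqs(0.3),
#'   env = env_uniform(0, 4), m = 0.1,
#'   model = "GEM", rr31 = 3, w = 0.5, env_or = 1.5
#' )
#' @export
population_spec <- function(n,
                            genotype_freqs,
                            env,
                            m,
                            model = c("GM", "EM", "GEM", "AM", "CUSTOM"),
                            rr31 = 1,
                            w = 0,
                            env_or = 1,
                            causal_gene = 1L,
                            causal_env = 1L,
                            coef_table = NULL) {
  model <- match.arg(model)
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1, n == floor(n))

  if (is.numeric(genotype_freqs)) genotype_freqs <- list(genotype_freqs)
  for (fr in genotype_freqs) {
    if (!is.numeric(fr) || length(fr) != 3L || any(!is.finite(fr)) ||
        any(fr < 0) || abs(sum(fr) - 1) > 1e-9) {
      stop("each genotype-frequency triple must be nonnegative and sum to 1 (tolerance 1e-9)",
           call. = FALSE)
    }
  }
  if (is_gxe_env(env)) env <- list(env)
  if (!all(vapply(env, is_gxe_env, logical(1)))) {
    stop("`env` must be one or more exposure distributions (see env_normal() etc.)",
         call. = FALSE)
  }

  if (!is.numeric(m) || length(m) != 1L || !is.finite(m) || m <= 0 || m >= 1) {
    stop("`m` (disease frequency) must lie in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(rr31) || rr31 < 1) stop("`rr31` must be >= 1", call. = FALSE)
  if (!is.numeric(w) || w < 0 || w > 1) stop("`w` must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(env_or) || env_or <= 0) stop("`env_or` must be positive", call. = FALSE)

  G <- length(genotype_freqs)
  E <- length(env)
  causal_gene <- as.integer(causal_gene)
  causal_env <- as.integer(causal_env)
  if (any(causal_gene < 1L) || any(causal_gene > G)) {
    stop("`causal_gene` out of range", call. = FALSE)
  }
  if (any(causal_env < 1L) || any(causal_env > E)) {
    stop("`causal_env` out of range", call. = FALSE)
  }
  if (model == "CUSTOM") {
    if (is.null(coef_table) || !inherits(coef_table, "mlm_coef_table")) {
      stop("model \"CUSTOM\" requires a coefficient table (see coef_table())",
           call. = FALSE)
    }
    if (coef_table$n_genes != length(causal_gene) ||
        coef_table$n_envs != length(causal_env)) {
      stop("coefficient-table dimensions do not match the causal factor counts",
           call. = FALSE)
    }
  } else {
    if (length(causal_gene) != 1L || length(causal_env) != 1L) {
      stop("models solved from epidemiological inputs use exactly one causal gene and one causal environment",
           call. = FALSE)
    }
  }

  structure(list(n = as.integer(n), n_genes = G, n_envs = E,
                 genotype_freqs = genotype_freqs, env = env, m = m,
                 model = model, rr31 = rr31, w = w, env_or = env_or,
                 causal_gene = causal_gene, causal_env = causal_env,
                 coef_table = coef_table),
            class = "population_spec")
}

#' @export
print.population_spec <- function(x, ...) {
  cat(sprintf("<population spec: n = %d, %d gene(s), %d environment(s)>\n",
              x$n, x$n_genes, x$n_envs))
  cat(sprintf("  model = %s, m = %g", x$model, x$m))
  if (x$model != "CUSTOM") {
    cat(sprintf(", RR31 = %g, W = %g, env OR = %g", x$rr31, x$w, x$env_or))
  }
  cat("\n")
  invisible(x)
}

#' Draw a random valid population specification
#'
#' Convenience generator for property checks and worked examples: samples an
#' interaction model (unless given), an allele frequency uniformly in
#' [0.1, 0.9] (converted to Hardy-Weinberg genotype frequencies), a disease
#' frequency `m` in [0.02, 0.3], `rr31` in [1, 5] (fixed at 1 for `"EM"`,
#' where genetics must not alter risk), `w` in [0, 1], an environmental odds
#' ratio in [1.1, 2], and a nonnegative-support exposure distribution
#' (uniform or empirical discrete). Draws whose parameter combination is
#' infeasible (e.g. a disease frequency and relative risk jointly demanding
#' a genotype risk of 1 or more) are rejected and redrawn, so the returned
#' specification is always solvable. Uses the current RNG state.
#'
#' @param n Sample size stored in the specification.
#' @param model Interaction model, or `NULL` to pick one of GM, EM, GEM, AM
#'   at random.
#' @return A [population_spec()].
#' @export
random_population_spec <- function(n = 1000L, model = NULL) {
  for (attempt in 1:1000) {
    mod <- if (is.null(model)) sample(c("GM", "EM", "GEM", "AM"), 1L) else model
    p <- stats::runif(1, 0.1, 0.9)
    m <- stats::runif(1, 0.02, 0.3)
    rr31 <- if (mod == "EM") 1 else stats::runif(1, 1, 5)
    w <- stats::runif(1)
    env_or <- stats::runif(1, 1.1, 2)
    env <- if (stats::runif(1) < 0.5) {
      env_uniform(0, stats::runif(1, 1, 5))
    } else {
      k <- sample(2:5, 1L)
      pr <- stats::runif(k)
      env_discrete(seq(0, k - 1), pr / sum(pr))
    }
    spec <- population_spec(n = n, genotype_freqs = hwe_genotype_freqs(p),
                            env = env, m = m, model = mod, rr31 = rr31,
                            w = w, env_or = env_or)
    if (!inherits(try(solve_coefficients(spec), silent = TRUE), "try-error")) {
      return(spec)
    }
  }
  stop("failed to draw a feasible specification in 1000 attempts", call. = FALSE)
}
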