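#' Environmental exposure distributions
#'
#' Constructors for the exposure law of one environmental factor. Exposures
#' can follow a predefined parametric distribution (normal or uniform) or an
#' empirical discrete distribution given as support values with probabilities.
#'
#' @param mean,sd Mean and standard deviation of a normal exposure law
#'   (`sd > 0`).
#' @param min,max Bounds of a uniform exposure law (`min < max`).
#' @param values Numeric vector of distinct exposure levels of an empirical
#'   discrete law.
#' @param probs Probabilities attached to `values`; must be nonnegative and
#'   sum to 1 (tolerance 1e-9).
#'
#' @return An object of class `gxe_env` describing the distribution.
#'
#' @examples
#' env_normal(0, 1)
#' env_uniform(0, 4)
#' env_discrete(c(0, 1, 2), c(0.5, 0.3, 0.2))
#'
#' @name environment-distributions
NULL

#' @rdname environment-distributions
#' @export
env_normal <- function(mean = 0, sd = 1) {
  stopifnot(is.numeric(mean), length(mean) == 1L, is.finite(mean),
            is.numeric(sd), length(sd) == 1L, is.finite(sd))
  if (sd <= 0) stop("`sd` must be positive", call. = FALSE)
  structure(list(kind = "normal", mean = mean, sd = sd), class = "gxe_env")
}

#' @rdname environment-distributions
#' @export
env_uniform <- function(min = 0, max = 1) {
  stopifnot(is.numeric(min), length(min) == 1L, is.finite(min),
            is.numeric(max), length(max) == 1L, is.finite(max))
  if (min >= max) stop("`min` must be strictly less than `max`", call. = FALSE)
  structure(list(kind = "uniform", min = min, max = max), class = "gxe_env")
}

#' @rdname environment-distributions
#' @export
env_discrete <- function(values, probs) {
  stopifnot(is.numeric(values), is.numeric(probs),
            length(values) == length(probs), length(values) >= 1L,
            all(is.finite(values)), all(is.finite(probs)))
  if (anyDuplicated(values)) {
    stop("`values` must be distinct exposure levels", call. = FALSE)
  }
  if (any(probs < 0)) stop("probabilities must be nonnegative", call. = FALSE)
  if (abs(sum(probs) - 1) > 1e-9) {
    stop("probabilities must sum to 1 (tolerance 1e-9)", call. = FALSE)
  }
  o <- order(values)
  structure(list(kind = "discrete", values = values[o], probs = probs[o]),
            class = "gxe_env")
}

#' @export
print.gxe_env <- function(x, ...) {
  switch(x$kind,
    normal = cat(sprintf("<environmental exposure: normal(mean = %g, sd = %g)>\n",
                         x$mean, x$sd)),
    uniform = cat(sprintf("<environmental exposure: uniform(%g, %g)>\n",
                          x$min, x$max)),
    discrete = {
      cat("<environmental exposure: empirical discrete>\n")
      print(stats::setNames(x$probs, format(x$values)))
    })
  invisible(x)
}

is_gxe_env <- function(x) inherits(x, "gxe_env")

#' Draw exposures from an environmental distribution
#'
#' @param env A [`gxe_env`][environment-distributions] object.
#' @param n Number of draws.
#' @return Numeric vector of length `n`. Uses the current RNG state, so
#'   results are reproducible under [set.seed()].
#' @export
env_sample <- function(env, n) {
  stopifnot(is_gxe_env(env), n >= 0)
  switch(env$kind,
    normal = stats::rnorm(n, env$mean, env$sd),
    uniform = stats::runif(n, env$min, env$max),
    discrete = {
      if (length(env$values) == 1L) rep(env$values, n)
      else sample(env$values, n, replace = TRUE, prob = env$probs)
    })
}

# lower bound of the support; used to decide whether the marginal risk is
# monotone in the slope coefficient
env_support_min <- function(env) {
  switch(env$kind,
    normal = -Inf,
    uniform = env$min,
    discrete = min(env$values))
}

# TRUE when the distribution is a single point mass (closed-form solves apply)
env_is_point_mass <- function(env) {
  env$kind == "discrete" && length(env$values) == 1L
}

# Gauss-Legendre base nodes on [-1, 1], cached; rescaled per interval.
.gl_cache <- new.env(parent = emptyenv())

gl_nodes <- function(a, b, n = 256L) {
  key <- as.character(n)
  base <- .gl_cache[[key]]
  if (is.null(base)) {
    base <- pracma::gaussLegendre(n, -1, 1)
    .gl_cache[[key]] <- base
  }
  list(x = (a + b) / 2 + (b - a) / 2 * base$x,
       w = (b - a) / 2 * base$w)
}

#' Expectation of a function of the exposure
#'
#' Computes `E[f(X)]` for an exposure distribution: an exact weighted sum for
#' discrete laws, and fixed-scheme Gauss-Legendre quadrature (256 nodes) for
#' continuous ones. For the normal law the integral is truncated to
#' `mean +/- 8 sd` (tail mass below 1e-15).
#'
#' @param env A [`gxe_env`][environment-distributions] object.
#' @param f Vectorized function of the exposure value.
#' @return Scalar expectation.
#' @keywords internal
#' @export
env_expectation <- function(env, f) {
  stopifnot(is_gxe_env(env), is.function(f))
  switch(env$kind,
    discrete = sum(env$probs * f(env$values)),
    uniform = {
      gl <- gl_nodes(env$min, env$max)
      sum(gl$w * f(gl$x)) / (env$max - env$min)
    },
    normal = {
      gl <- gl_nodes(env$mean - 8 * env$sd, env$mean + 8 * env$sd)
      sum(gl$w * f(gl$x) * stats::dnorm(gl$x, env$mean, env$sd))
    })
}
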