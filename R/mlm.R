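#' Logistic function
#'
#' Maps a log-odds value to a probability, `1 / (1 + exp(-z))`. The result is
#' mathematically confined to (0, 1) and is monotone increasing in `z`.
#'
#' @param z Numeric vector of finite log-odds.
#' @return Probabilities of the same length as `z`.
#' @examples
#' logistic(0)       # 0.5
#' logistic(log(3))  # 0.75
#' @export
logistic <- function(z) {
  if (!is.numeric(z) || any(!is.finite(z))) {
    stop("`z` must be finite numeric log-odds", call. = FALSE)
  }
  stats::plogis(z)
}

#' Per-genotype logistic risk coefficients
#'
#' For a one-gene model the multi-logistic penetrance model reduces to three
#' logistic functions, one per genotype of a biallelic SNP: the reference
#' homozygote (index 1), the heterozygote (2) and the high-risk homozygote
#' (3). `alpha[i]` is the basal log-odds of disease for genotype `i`;
#' `beta[i]` is the log-odds increment per one unit of environmental
#' exposure, i.e. the log odds ratio of an `x + 1` versus `x` exposure
#' contrast.
#'
#' @param alpha Numeric length-3 vector of intercepts.
#' @param beta Numeric length-3 vector of exposure slopes.
#' @return An object of class `mlm_coefficients`.
#' @examples
#' mlm_coefficients(alpha = c(-2, -2, -2), beta = c(0.1, 0.4, 0.9))
#' @export
mlm_coefficients <- function(alpha, beta) {
  stopifnot(is.numeric(alpha), is.numeric(beta))
  if (length(alpha) != 3L || length(beta) != 3L) {
    stop("a one-gene model needs exactly three (alpha, beta) pairs",
         call. = FALSE)
  }
  if (any(!is.finite(alpha)) || any(!is.finite(beta))) {
    stop("coefficients must be finite", call. = FALSE)
  }
  structure(list(alpha = as.numeric(alpha), beta = as.numeric(beta)),
            class = "mlm_coefficients")
}

#' @export
print.mlm_coefficients <- function(x, ...) {
  cat("<multi-logistic coefficients (one gene)>\n")
  m <- rbind(alpha = x$alpha, beta = x$beta)
  colnames(m) <- c("AA (1)", "Aa (2)", "aa (3)")
  print(m)
  invisible(x)
}

check_genotype_index <- function(genotype) {
  if (!is.numeric(genotype) || any(!(genotype %in% c(1, 2, 3)))) {
    stop("genotype index must be 1 (AA), 2 (Aa) or 3 (aa)", call. = FALSE)
  }
  as.integer(genotype)
}

#' Disease risk for one genotype and one exposure level
#'
#' Evaluates the one gene-one environment penetrance
#' `logistic(alpha[i] + beta[i] * x)`. `genotype` and `exposure` are
#' recycled against each other.
#'
#' @param coeffs An [mlm_coefficients()] object.
#' @param genotype Genotype index in `{1, 2, 3}`.
#' @param exposure Numeric exposure level(s).
#' @return Risk probabilities in (0, 1).
#' @examples
#' co <- mlm_coefficients(c(-2, -2, -2), c(0.5, 0.5, 0.5))
#' genotype_risk(co, 1, 4)  # logistic(0) = 0.5
#' @export
genotype_risk <- function(coeffs, genotype, exposure) {
  stopifnot(inherits(coeffs, "mlm_coefficients"), is.numeric(exposure),
            all(is.finite(exposure)))
  g <- check_genotype_index(genotype)
  logistic(coeffs$alpha[g] + coeffs$beta[g] * exposure)
}

#' Coefficient table for multi-gene, multi-environment models
#'
#' The general penetrance model attaches one logistic function to every
#' multi-locus genotype combination: an intercept `alpha` and a slope vector
#' `beta` with one entry per environmental covariate. A table over `G` genes
#' must contain all `3^G` genotype combinations, keyed by the comma-joined
#' genotype indices (e.g. `"1,3,2"`).
#'
#' @param entries Named list; names are genotype-tuple keys, values are lists
#'   with elements `alpha` (scalar) and `beta` (length-`E` vector).
#' @return An object of class `mlm_coef_table` with fields `n_genes`,
#'   `n_envs` and `entries`.
#' @seealso [general_risk()], [read_coef_table()]
#' @export
coef_table <- function(entries) {
  stopifnot(is.list(entries), length(entries) >= 1L)
  keys <- names(entries)
  if (is.null(keys) || any(keys == "")) {
    stop("all entries must be named by genotype tuples like \"1,3,2\"",
         call. = FALSE)
  }
  split_keys <- strsplit(keys, ",", fixed = TRUE)
  g <- unique(lengths(split_keys))
  if (length(g) != 1L) stop("genotype tuples have inconsistent lengths", call. = FALSE)
  expected <- apply(expand.grid(rep(list(1:3), g)), 1L,
                    paste, collapse = ",")
  norm_keys <- vapply(split_keys, function(k) {
    paste(check_genotype_index(as.numeric(k)), collapse = ",")
  }, character(1))
  if (!setequal(norm_keys, expected) || anyDuplicated(norm_keys)) {
    stop(sprintf("table must contain each of the %d genotype combinations exactly once",
                 3L^g), call. = FALSE)
  }
  e_len <- unique(vapply(entries, function(v) length(v$beta), integer(1)))
  if (length(e_len) != 1L) {
    stop("all beta vectors must have the same length", call. = FALSE)
  }
  for (v in entries) {
    if (!is.numeric(v$alpha) || length(v$alpha) != 1L || !is.finite(v$alpha) ||
        !is.numeric(v$beta) || any(!is.finite(v$beta))) {
      stop("each entry needs a finite scalar `alpha` and finite `beta` vector",
           call. = FALSE)
    }
  }
  entries <- stats::setNames(entries, norm_keys)[expected]
  structure(list(n_genes = g, n_envs = e_len, entries = entries),
            class = "mlm_coef_table")
}

#' @export
print.mlm_coef_table <- function(x, ...) {
  cat(sprintf("<coefficient table: %d gene(s) x %d environment(s), %d entries>\n",
              x$n_genes, x$n_envs, length(x$entries)))
  invisible(x)
}

#' Convert one-gene coefficients to a general coefficient table
#'
#' @param coeffs An [mlm_coefficients()] object.
#' @return An [coef_table()] with `G = 1`, `E = 1`.
#' @export
coef_table_from_coefficients <- function(coeffs) {
  stopifnot(inherits(coeffs, "mlm_coefficients"))
  coef_table(stats::setNames(
    lapply(1:3, function(i) list(alpha = coeffs$alpha[i],
                                 beta = coeffs$beta[i])),
    as.character(1:3)))
}

#' Disease risk under a general coefficient table
#'
#' Evaluates `logistic(alpha + sum(beta * exposures))` for the table entry
#' selected by the genotype tuple. For a one-gene, one-environment table this
#' agrees exactly with [genotype_risk()].
#'
#' @param table An [coef_table()] object.
#' @param genotypes Integer vector of `n_genes` genotype indices.
#' @param exposures Numeric vector of `n_envs` exposure values.
#' @return A single risk probability.
#' @export
general_risk <- function(table, genotypes, exposures) {
  stopifnot(inherits(table, "mlm_coef_table"))
  g <- check_genotype_index(genotypes)
  if (length(g) != table$n_genes) {
    stop(sprintf("expected %d genotype indices, got %d",
                 table$n_genes, length(g)), call. = FALSE)
  }
  if (!is.numeric(exposures) || length(exposures) != table$n_envs ||
      any(!is.finite(exposures))) {
    stop(sprintf("expected %d finite exposure values", table$n_envs),
         call. = FALSE)
  }
  key <- paste(g, collapse = ",")
  entry <- table$entries[[key]]
  if (is.null(entry)) stop(sprintf("no entry for genotype tuple %s", key),
                           call. = FALSE)
  logistic(entry$alpha + sum(entry$beta * exposures))
}

#' Read / write a coefficient table as JSON
#'
#' Tables are serialized with genotype-tuple keys (`"1,3,2"`) mapping to
#' objects `{"alpha": number, "beta": [numbers]}`.
#'
#' @param path File path.
#' @param table An [coef_table()] object.
#' @return `read_coef_table()` returns an `mlm_coef_table`;
#'   `write_coef_table()` returns `path` invisibly.
#' @export
read_coef_table <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  coef_table(lapply(raw, function(v) {
    list(alpha = as.numeric(v$alpha), beta = as.numeric(unlist(v$beta)))
  }))
}

#' @rdname read_coef_table
#' @export
write_coef_table <- function(table, path) {
  stopifnot(inherits(table, "mlm_coef_table"))
  out <- lapply(table$entries, function(v) {
    list(alpha = v$alpha, beta = as.list(v$beta))
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Total (marginal) risk of a genotype over the exposure distribution
#'
#' The total risk of genotype `i` is the expectation of its penetrance over
#' the exposure law, `TR_i = E_x[logistic(alpha_i + beta_i * x)]`: an exact
#' weighted sum for discrete environments and deterministic Gauss-Legendre
#' quadrature for continuous ones (see [env_expectation()]).
#'
#' @param alpha,beta Scalar intercept and exposure slope for the genotype.
#' @param env A [`gxe_env`][environment-distributions] exposure distribution.
#' @return Scalar probability in (0, 1); strictly increasing in `alpha`.
#' @examples
#' total_risk(0, log(3), env_discrete(c(0, 1), c(0.5, 0.5)))  # 0.625
#' @export
total_risk <- function(alpha, beta, env) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
            is.numeric(beta), length(beta) == 1L, is.finite(beta),
            is_gxe_env(env))
  if (beta == 0) return(logistic(alpha))
  env_expectation(env, function(x) stats::plogis(alpha + beta * x))
}

#' Relative risk between two genotypes
#'
#' Ratio of total risks, `RR_kl = TR_k / TR_l`.
#'
#' @param tr_k,tr_l Total risks; `tr_l` must be positive.
#' @return Scalar relative risk.
#' @export
relative_risk <- function(tr_k, tr_l) {
  stopifnot(is.numeric(tr_k), is.numeric(tr_l))
  if (any(tr_l <= 0)) stop("the reference total risk must be positive",
                           call. = FALSE)
  tr_k / tr_l
}

#' Heterozygote relative risk from the inheritance weight
#'
#' Places the heterozygote relative risk between the two homozygotes on the
#' relative-risk scale: `RR21 = 1 + W * (RR31 - 1)`. `W = 0` gives a
#' recessive effect (heterozygote risk equals the reference homozygote),
#' `W = 1` a dominant effect (equals the high-risk homozygote), and
#' `0 < W < 1` a co-dominant effect. The result always satisfies
#' `1 <= RR21 <= RR31`.
#'
#' @param rr31 Relative risk of the high-risk homozygote, `>= 1`.
#' @param w Inheritance weight in `[0, 1]`.
#' @return Scalar `RR21`.
#' @examples
#' heterozygote_rr(3, 0)    # recessive: 1
#' heterozygote_rr(3, 1)    # dominant: 3
#' heterozygote_rr(3, 0.5)  # co-dominant: 2
#' @export
heterozygote_rr <- function(rr31, w) {
  stopifnot(is.numeric(rr31), length(rr31) == 1L, is.finite(rr31),
            is.numeric(w), length(w) == 1L, is.finite(w))
  if (rr31 < 1) stop("`rr31` must be >= 1 (risks are relative to the reference homozygote)",
                     call. = FALSE)
  if (w < 0 || w > 1) stop("`w` must lie in [0, 1]", call. = FALSE)
  1 + w * (rr31 - 1)
}
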