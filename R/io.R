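#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON, a YAML subset) configuration describing a
#' simulation run and validates every field, applying defaults where the
#' file omits optional parameters (each default is reported with a message).
#'
#' Required fields: `n`, `m`, `model`, `genes` (a list whose items give
#' either `maf` — converted via Hardy-Weinberg — or `genotype_freqs`), and
#' `envs` (a list of items with `kind: normal|uniform|discrete` and the
#' matching parameters). Optional: `rr31` (default 1), `w` (0), `env_or`
#' (1), `causal_gene`/`causal_env` (1), `coef_table` (path, required when
#' `model: CUSTOM`), `seed` (1), `out` (`"gxesim-output"`),
#' `replicates` (1), `emit_risk` (true).
#'
#' @param path Path to the configuration file.
#' @return An object of class `run_config`: the validated
#'   [population_spec()] plus run settings.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path),
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  build_run_config(raw, dir = dirname(path))
}

default_field <- function(raw, name, default) {
  if (is.null(raw[[name]])) {
    message(sprintf("config: `%s` not given, using default %s",
                    name, format(default)))
    default
  } else {
    raw[[name]]
  }
}

build_run_config <- function(raw, dir = ".") {
  stopifnot(is.list(raw))
  for (field in c("n", "m", "model", "genes", "envs")) {
    if (is.null(raw[[field]])) {
      stop(sprintf("config: required field `%s` is missing", field),
           call. = FALSE)
    }
  }
  if (!is.numeric(raw$m) || length(raw$m) != 1L || raw$m <= 0 || raw$m >= 1) {
    stop("config: `m` (disease_freq) must lie in (0, 1)", call. = FALSE)
  }
  model <- match.arg(toupper(raw$model), c("GM", "EM", "GEM", "AM", "CUSTOM"))

  genes <- raw$genes
  if (!is.list(genes) || length(genes) == 0L) {
    stop("config: `genes` must be a non-empty list", call. = FALSE)
  }
  genotype_freqs <- lapply(genes, function(g) {
    if (!is.null(g$genotype_freqs)) as.numeric(g$genotype_freqs)
    else if (!is.null(g$maf)) hwe_genotype_freqs(as.numeric(g$maf))
    else stop("config: each gene needs `maf` or `genotype_freqs`",
              call. = FALSE)
  })

  envs <- raw$envs
  if (!is.list(envs) || length(envs) == 0L) {
    stop("config: `envs` must be a non-empty list", call. = FALSE)
  }
  env <- lapply(envs, function(e) {
    kind <- match.arg(e$kind, c("normal", "uniform", "discrete"))
    switch(kind,
      normal = env_normal(as.numeric(e$mean), as.numeric(e$sd)),
      uniform = env_uniform(as.numeric(e$min), as.numeric(e$max)),
      discrete = env_discrete(as.numeric(unlist(e$values)),
                              as.numeric(unlist(e$probs))))
  })

  tbl <- NULL
  if (model == "CUSTOM") {
    if (is.null(raw$coef_table)) {
      stop("config: model CUSTOM requires `coef_table` (path to a coefficient JSON)",
           call. = FALSE)
    }
    tbl_path <- raw$coef_table
    if (!file.exists(tbl_path)) tbl_path <- file.path(dir, raw$coef_table)
    if (!file.exists(tbl_path)) {
      stop(sprintf("config: coefficient table not found: %s", raw$coef_table),
           call. = FALSE)
    }
    tbl <- read_coef_table(tbl_path)
  }

  spec <- population_spec(
    n = raw$n,
    genotype_freqs = genotype_freqs,
    env = env,
    m = raw$m,
    model = model,
    rr31 = default_field(raw, "rr31", 1),
    w = default_field(raw, "w", 0),
    env_or = default_field(raw, "env_or", 1),
    causal_gene = default_field(raw, "causal_gene", 1L),
    causal_env = default_field(raw, "causal_env", 1L),
    coef_table = tbl)

  replicates <- default_field(raw, "replicates", 1L)
  if (!is.numeric(replicates) || replicates < 1) {
    stop("config: `replicates` must be a positive integer", call. = FALSE)
  }
  structure(list(spec = spec,
                 seed = as.integer(default_field(raw, "seed", 1L)),
                 out = default_field(raw, "out", "gxesim-output"),
                 replicates = as.integer(replicates),
                 emit_risk = isTRUE(default_field(raw, "emit_risk", TRUE)),
                 raw = raw),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("<run config: %d replicate(s), seed %d, out = %s>\n",
              x$replicates, x$seed, x$out))
  print(x$spec)
  invisible(x)
}

#' Write / read a simulated dataset as TSV
#'
#' Datasets are written as tab-separated text with a mandatory header:
#' columns `id`, `G1..Gg` (risk-allele counts 0/1/2), `E1..Ee` (raw
#' exposures), optionally `risk`, and `status` (0/1). No missing values.
#'
#' @param dataset A `gxe_dataset`.
#' @param path Output file path.
#' @param emit_risk Include the latent risk column.
#' @return `write_dataset()` returns `path` invisibly.
#' @export
write_dataset <- function(dataset, path, emit_risk = TRUE) {
  df <- as.data.frame(dataset, include_risk = emit_risk)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @param spec Optionally, the generating [population_spec()], so that the
#'   returned object can feed [summarize_dataset()].
#' @param solution Optionally, the `gxe_solution` provenance.
#' @return `read_dataset()` returns a `gxe_dataset` (with `NA` risks if the
#'   file was written without the risk column).
#' @export
read_dataset <- function(path, spec = NULL, solution = NULL) {
  df <- utils::read.delim(path, check.names = FALSE)
  gcols <- grep("^G[0-9]+$", names(df), value = TRUE)
  ecols <- grep("^E[0-9]+$", names(df), value = TRUE)
  if (length(gcols) == 0L || length(ecols) == 0L || is.null(df$status)) {
    stop("not a simulated dataset: expected G*/E*/status columns", call. = FALSE)
  }
  structure(list(
    genotypes = as.matrix(df[gcols]) + 1L,
    exposures = as.matrix(df[ecols]),
    risk = if (is.null(df$risk)) rep(NA_real_, nrow(df)) else df$risk,
    status = as.integer(df$status),
    spec = spec, seed = NA_integer_, solution = solution),
    class = "gxe_dataset")
}

summary_to_list <- function(s) {
  lapply(unclass(s), function(v) {
    if (is.numeric(v)) ifelse(is.finite(v), v, NA) else v
  })
}

write_summary_json <- function(summary, path) {
  jsonlite::write_json(summary_to_list(summary), path, auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

solution_to_list <- function(sol) {
  list(model = sol$model,
       alpha = sol$coefficients$alpha,
       beta = sol$coefficients$beta,
       target_tr = sol$target_tr,
       achieved_tr = sol$achieved_tr,
       max_residual = sol$max_residual,
       rr21 = sol$rr21, rr31 = sol$rr31)
}

#' Run a configured simulation end to end
#'
#' For each replicate: derive the replicate seed (`seed + replicate - 1`),
#' simulate the population, summarize it, and write the dataset TSV and
#' summary JSON. The solved coefficients (identical across replicates), the
#' echoed configuration and a plain-text log are written alongside.
#' Coefficient solving happens before any file is created, so an infeasible
#' configuration fails cleanly without partial outputs.
#'
#' @param config A `run_config` from [load_run_config()], or a path to a
#'   configuration file.
#' @return Invisibly, a list with the output paths and the per-replicate
#'   summaries.
#' @export
run_simulation <- function(config) {
  if (is.character(config)) config <- load_run_config(config)
  stopifnot(inherits(config, "run_config"))
  spec <- config$spec

  t0 <- proc.time()[["elapsed"]]
  solution <- if (spec$model == "CUSTOM") NULL else solve_coefficients(spec)

  out <- config$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  config_path <- file.path(out, "config.yaml")
  yaml::write_yaml(config$raw, config_path)

  coef_path <- file.path(out, "coefficients.json")
  if (is.null(solution)) {
    write_coef_table(spec$coef_table, coef_path)
  } else {
    jsonlite::write_json(solution_to_list(solution), coef_path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  dataset_paths <- character(config$replicates)
  summary_paths <- character(config$replicates)
  summaries <- vector("list", config$replicates)
  for (r in seq_len(config$replicates)) {
    seed_r <- config$seed + r - 1L
    sim <- simulate_population(spec, seed_r)
    summaries[[r]] <- summarize_dataset(sim)
    dataset_paths[r] <- file.path(out, sprintf("dataset_%d.tsv", r))
    summary_paths[r] <- file.path(out, sprintf("summary_%d.json", r))
    write_dataset(sim, dataset_paths[r], emit_risk = config$emit_risk)
    write_summary_json(summaries[[r]], summary_paths[r])
  }

  log_path <- file.path(out, "run.log")
  digest <- unname(tools::md5sum(config_path))
  lines <- c(
    sprintf("config md5: %s", digest),
    sprintf("root seed: %d, replicates: %d", config$seed, config$replicates),
    if (!is.null(solution)) {
      sprintf("solver: model %s, max residual %.3g", solution$model,
              solution$max_residual)
    } else "solver: custom coefficient table",
    vapply(seq_len(config$replicates), function(r) {
      sprintf("replicate %d: seed %d, prevalence %.4f", r,
              config$seed + r - 1L, summaries[[r]]$empirical_prevalence)
    }, character(1)),
    sprintf("wall-time (s, informational): %.2f",
            proc.time()[["elapsed"]] - t0))
  writeLines(lines, log_path)

  invisible(list(out = out, config = config_path, coefficients = coef_path,
                 datasets = dataset_paths, summaries_json = summary_paths,
                 log = log_path, summaries = summaries))
}
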