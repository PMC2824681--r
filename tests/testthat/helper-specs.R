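# Shared fixtures, built in code.

spec_for <- function(model, n = 1000L, p = 0.5, env = env_uniform(0, 4),
                     m = 0.1, rr31 = 3, w = 0.5, env_or = 1.5) {
  if (model == "EM") rr31 <- 1
  population_spec(n = n, genotype_freqs = hwe_genotype_freqs(p), env = env,
                  m = m, model = model, rr31 = rr31, w = w, env_or = env_or)
}

# exhaustive weighted sum over a discrete support, independent of the
# quadrature code path
brute_force_tr <- function(alpha, beta, env) {
  stopifnot(env$kind == "discrete")
  sum(env$probs / (1 + exp(-(alpha + beta * env$values))))
}

write_config <- function(path, ...) {
  yaml::write_yaml(list(...), path)
  path
}

base_config <- function(out, n = 500, model = "AM", m = 0.1, rr31 = 3,
                        w = 1, env_or = 2, seed = 11, replicates = 1, ...) {
  list(n = n, m = m, model = model, rr31 = rr31, w = w, env_or = env_or,
       genes = list(list(maf = 0.5)),
       envs = list(list(kind = "uniform", min = 0, max = 4)),
       seed = seed, out = out, replicates = replicates, ...)
}
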