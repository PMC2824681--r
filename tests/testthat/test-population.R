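test_that("randomly selected allele frequencies are uniform on [0.1, 0.9]", {
  set.seed(1)
  f <- sample_allele_freqs(1e5)
  expect_true(all(f >= 0.1 & f <= 0.9))
  # uniform mean 0.5, sd 0.8/sqrt(12)
  se <- (0.8 / sqrt(12)) / sqrt(length(f))
  expect_lt(abs(mean(f) - 0.5), 3 * se)
  set.seed(99); a <- sample_allele_freqs(10)
  set.seed(99); b <- sample_allele_freqs(10)
  expect_identical(a, b)
})

test_that("Hardy-Weinberg frequencies follow p^2, 2pq, q^2", {
  expect_equal(hwe_genotype_freqs(0.5), c(0.25, 0.5, 0.25))
  expect_equal(hwe_genotype_freqs(0.9), c(0.81, 0.18, 0.01))
  set.seed(2)
  for (p in runif(1000, 1e-6, 1 - 1e-6)) {
    expect_equal(sum(hwe_genotype_freqs(p)), 1)
  }
  expect_error(hwe_genotype_freqs(0), "strictly")
  expect_error(hwe_genotype_freqs(1.2), "strictly")
})

test_that("genotype assignment reproduces the genotype frequencies", {
  set.seed(3)
  g <- assign_genotypes(100, c(1, 0, 0))
  expect_true(all(g == 1L))

  n <- 1e5
  fr <- c(0.25, 0.5, 0.25)
  g <- assign_genotypes(n, fr)
  emp <- tabulate(g, 3) / n
  se <- sqrt(fr * (1 - fr) / n)
  expect_true(all(abs(emp - fr) < 3 * se))

  set.seed(8); a <- assign_genotypes(50, fr)
  set.seed(8); b <- assign_genotypes(50, fr)
  expect_identical(a, b)
  expect_error(assign_genotypes(10, c(0.5, 0.2, 0.2)), "summing to 1")

  # multiple genes give one column each
  gm <- assign_genotypes(20, list(fr, c(0.1, 0.2, 0.7)))
  expect_identical(dim(gm), c(20L, 2L))
  expect_identical(colnames(gm), c("G1", "G2"))
})

test_that("exposure assignment reproduces the exposure distributions", {
  set.seed(4)
  x <- assign_exposures(100, env_discrete(2.5, 1))
  expect_true(all(x == 2.5))

  n <- 1e5
  x <- assign_exposures(n, env_normal(0, 1))
  expect_lt(abs(mean(x)), 3 / sqrt(n))

  x <- assign_exposures(n, env_discrete(c(0, 1), c(0.3, 0.7)))
  emp <- mean(x == 1)
  expect_lt(abs(emp - 0.7), 3 * sqrt(0.3 * 0.7 / n))

  xm <- assign_exposures(50, list(env_uniform(0, 1), env_normal(5, 2)))
  expect_identical(dim(xm), c(50L, 2L))
  expect_true(all(xm[, 1] >= 0 & xm[, 1] <= 1))
})

test_that("risk assignment uses only the causal columns", {
  set.seed(5)
  n <- 500
  co <- mlm_coefficients(c(-2.5, -2, -1.5), c(0.3, 0.5, 0.7))
  genotypes <- assign_genotypes(n, list(c(0.25, 0.5, 0.25), c(0.2, 0.3, 0.5)))
  exposures <- assign_exposures(n, list(env_uniform(0, 4), env_normal(0, 1)))
  risk <- assign_risk(genotypes, exposures, co, causal_gene = 1, causal_env = 1)
  expect_true(all(risk >= 0 & risk <= 1))

  # spot-check against direct per-row evaluation
  for (i in sample(n, 100)) {
    expect_identical(risk[i],
                     unname(genotype_risk(co, genotypes[i, 1],
                                          exposures[i, 1])))
  }

  # permuting noise columns leaves the risks unchanged
  g2 <- genotypes; g2[, 2] <- sample(g2[, 2])
  x2 <- exposures; x2[, 2] <- sample(x2[, 2])
  expect_identical(assign_risk(g2, x2, co, 1, 1), risk)

  # genetic-only coefficients: risk is flat in the exposure
  gm_co <- mlm_coefficients(qlogis(c(0.05, 0.1, 0.2)), c(0, 0, 0))
  r1 <- assign_risk(genotypes, exposures, gm_co, 1, 1)
  x3 <- exposures; x3[, 1] <- x3[, 1] + 10
  expect_identical(assign_risk(genotypes, x3, gm_co, 1, 1), r1)

  expect_error(assign_risk(genotypes, exposures, co, causal_gene = 3),
               "out of range")
})

test_that("risk assignment under a general table matches direct evaluation", {
  set.seed(15)
  keys <- apply(expand.grid(1:3, 1:3), 1, paste, collapse = ",")
  tbl <- coef_table(setNames(lapply(keys, function(k) {
    list(alpha = rnorm(1, -2), beta = rnorm(2, 0, 0.4))
  }), keys))
  n <- 200
  genotypes <- assign_genotypes(n, list(c(0.3, 0.4, 0.3), c(0.25, 0.5, 0.25)))
  exposures <- assign_exposures(n, list(env_uniform(0, 2), env_normal(0, 1)))
  risk <- assign_risk(genotypes, exposures, tbl,
                      causal_gene = c(1, 2), causal_env = c(1, 2))
  for (i in sample(n, 50)) {
    expect_equal(risk[i], general_risk(tbl, genotypes[i, ], exposures[i, ]))
  }
})

test_that("status assignment is a strict Bernoulli threshold on the risk", {
  expect_identical(assign_status(rep(0, 100)), rep(0L, 100))
  expect_identical(assign_status(rep(1, 100)), rep(1L, 100))
  set.seed(6)
  n <- 1e5
  s <- assign_status(rep(0.3, n))
  expect_true(all(s %in% c(0L, 1L)))
  expect_lt(abs(mean(s) - 0.3), 3 * sqrt(0.3 * 0.7 / n))
  expect_error(assign_status(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the full pipeline is deterministic and recovers its targets", {
  spec <- spec_for("AM", n = 50000L, rr31 = 3, w = 1, env_or = 1.5)
  a <- simulate_population(spec, 123)
  b <- simulate_population(spec, 123)
  expect_identical(a[c("genotypes", "exposures", "risk", "status")],
                   b[c("genotypes", "exposures", "risk", "status")])
  expect_false(identical(a$status, simulate_population(spec, 124)$status))

  # prevalence recovery
  m <- spec$m; n <- spec$n
  expect_lt(abs(mean(a$status) - m), 3 * sqrt(m * (1 - m) / n))

  # genotype frequencies converge to the Hardy-Weinberg triple
  fr <- hwe_genotype_freqs(0.5)
  emp <- tabulate(a$genotypes[, 1], 3) / n
  expect_true(all(abs(emp - fr) < 3 * sqrt(fr * (1 - fr) / n)))

  # genetic-only model: per-genotype affected fractions estimate the total
  # risks and their ratio recovers rr31
  gm <- simulate_population(spec_for("GM", n = 100000L, rr31 = 3, w = 0), 7)
  tr <- gm$solution$target_tr
  for (i in 1:3) {
    idx <- gm$genotypes[, 1] == i
    expect_lt(abs(mean(gm$status[idx]) - tr[i]),
              3 * sqrt(tr[i] * (1 - tr[i]) / sum(idx)))
  }
  frac <- vapply(1:3, function(i) mean(gm$status[gm$genotypes[, 1] == i]),
                 numeric(1))
  expect_lt(abs(frac[3] / frac[1] - 3), 0.45)
})

test_that("infeasible specifications fail before any sampling", {
  bad <- population_spec(1000, c(0.9, 0.08, 0.02), env_uniform(0, 1),
                         m = 0.5, model = "GM", rr31 = 5, w = 0)
  expect_error(simulate_population(bad, 1), "infeasible")
})

test_that("custom-table simulation drives risk from the table", {
  set.seed(31)
  tbl <- coef_table_from_coefficients(
    mlm_coefficients(qlogis(c(0.02, 0.05, 0.3)), c(0, 0, 0)))
  spec <- population_spec(20000, hwe_genotype_freqs(0.5), env_uniform(0, 1),
                          m = 0.1, model = "CUSTOM", coef_table = tbl)
  sim <- simulate_population(spec, 77)
  expect_null(sim$solution)
  frac <- vapply(1:3, function(i) mean(sim$status[sim$genotypes[, 1] == i]),
                 numeric(1))
  tr <- c(0.02, 0.05, 0.3)
  for (i in 1:3) {
    ni <- sum(sim$genotypes[, 1] == i)
    expect_lt(abs(frac[i] - tr[i]), 3 * sqrt(tr[i] * (1 - tr[i]) / ni))
  }
})

test_that("fixed case-control subsampling keeps the requested counts", {
  spec <- spec_for("GM", n = 5000L, m = 0.2, rr31 = 2, w = 0.5)
  sim <- simulate_population(spec, 9)
  set.seed(10)
  sub <- sample_case_control(sim, 300, 300)
  expect_identical(sum(sub$status), 300L)
  expect_identical(sum(1L - sub$status), 300L)
  expect_identical(nrow(sub$genotypes), 600L)
  expect_error(sample_case_control(sim, 1e6, 10), "holds")
})
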