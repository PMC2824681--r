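test_that("target total risks follow the prevalence decomposition", {
  # no genetic effect: every genotype carries the overall frequency
  expect_equal(target_total_risks(0.1, c(0.25, 0.5, 0.25), 1, 0.7),
               c(0.1, 0.1, 0.1))
  # dominant inheritance: heterozygote matches the high-risk homozygote
  expect_equal(target_total_risks(0.1, c(0.25, 0.5, 0.25), 3, 1),
               c(0.04, 0.12, 0.12))
  # recessive inheritance: heterozygote matches the reference homozygote
  # (frozen from the closed form TR1 = m / (P1 + P2 + P3 * RR31) = 0.1/1.5)
  expect_equal(target_total_risks(0.1, c(0.25, 0.5, 0.25), 3, 0),
               c(1 / 15, 1 / 15, 0.2))

  # conservation holds exactly for random inputs
  set.seed(21)
  for (k in 1:50) {
    fr <- hwe_genotype_freqs(runif(1, 0.05, 0.95))
    m <- runif(1, 0.01, 0.4); rr31 <- runif(1, 1, 4); w <- runif(1)
    tr <- tryCatch(target_total_risks(m, fr, rr31, w),
                   error = function(e) NULL)
    if (is.null(tr)) next  # infeasible draw
    expect_equal(sum(fr * tr), m)
    expect_equal(tr[2] / tr[1], heterozygote_rr(rr31, w))
    expect_equal(tr[3] / tr[1], rr31)
  }

  # infeasible request is refused with the offending risk named
  expect_error(target_total_risks(0.5, c(0.9, 0.08, 0.02), 5, 0),
               "infeasible")
})

test_that("the genetic-only solver is the closed-form logit of the targets", {
  spec <- spec_for("GM", rr31 = 3, w = 1, p = 0.5)
  sol <- solve_gm(spec)
  tr <- target_total_risks(0.1, hwe_genotype_freqs(0.5), 3, 1)
  expect_equal(sol$coefficients$alpha, qlogis(tr))
  expect_identical(sol$coefficients$beta, rep(0, 3))
  expect_true(all(diff(sol$coefficients$alpha) >= 0))
  # beta = 0 makes the environment irrelevant: achieved = target exactly
  expect_equal(sol$achieved_tr, tr)

  # rr31 = 1 degenerates to the no-effect model
  flat <- solve_gm(spec_for("GM", rr31 = 1))
  expect_equal(max(flat$coefficients$alpha) - min(flat$coefficients$alpha), 0)
})

test_that("the environmental-only solver matches the overall frequency", {
  # degenerate exposure at 0: intercept is logit(m) exactly
  spec <- spec_for("EM", env = env_discrete(0, 1), env_or = 3, m = 0.2)
  sol <- solve_em(spec)
  expect_identical(sol$coefficients$alpha, rep(qlogis(0.2), 3))

  # worked two-point case: 0.5 logistic(a) + 0.5 logistic(a + ln 3) = 0.625
  # has the root a = 0
  spec <- spec_for("EM", env = env_discrete(c(0, 1), c(0.5, 0.5)),
                   env_or = 3, m = 0.625)
  sol <- solve_em(spec)
  expect_equal(sol$coefficients$alpha[1], 0, tolerance = 1e-10)
  expect_equal(sol$coefficients$beta, rep(log(3), 3))
  expect_lt(sol$max_residual, 1e-10)

  # genetics must not alter risk under EM
  bad <- spec_for("AM", rr31 = 3)
  bad$model <- "EM"
  expect_error(solve_em(bad), "rr31 = 1")
  # a vanishing exposure effect contradicts the model
  noeff <- spec_for("EM", env_or = 1)
  expect_error(solve_em(noeff), "env_or")
})

test_that("the additive solver matches every genotype's marginal risk", {
  for (env in list(env_uniform(0, 4), env_normal(1, 2),
                   env_discrete(c(0, 1, 2), c(0.5, 0.3, 0.2)))) {
    spec <- spec_for("AM", env = env, rr31 = 2.5, w = 0.4, env_or = 1.8)
    sol <- solve_am(spec)
    expect_equal(sol$coefficients$beta, rep(log(1.8), 3))
    tr <- target_total_risks(spec$m, hwe_genotype_freqs(0.5), 2.5, 0.4)
    for (i in 1:3) {
      expect_lt(abs(total_risk(sol$coefficients$alpha[i],
                               sol$coefficients$beta[i], env) - tr[i]), 1e-8)
    }
    expect_true(all(diff(sol$coefficients$alpha) >= 0))
  }
  expect_error(solve_am(spec_for("AM", env_or = 1)), "env_or")
})

test_that("the gene-modulated solver anchors the reference slope and derives the rest", {
  spec <- spec_for("GEM", env = env_uniform(0, 4), rr31 = 3, w = 0.5,
                   env_or = 1.5)
  sol <- solve_gem(spec)
  b <- sol$coefficients$beta
  expect_equal(b[1], log(1.5))
  expect_true(all(diff(b) >= 0))
  expect_equal(max(sol$coefficients$alpha) - min(sol$coefficients$alpha), 0)
  expect_lt(sol$max_residual, 1e-8)

  # rr31 = 1: equal total risks force equal slopes (reduces to EM)
  em_like <- solve_gem(spec_for("GEM", rr31 = 1))
  expect_equal(max(em_like$coefficients$beta) - min(em_like$coefficients$beta),
               0)

  # dominant inheritance: TR2 = TR3 with a shared intercept forces b2 = b3
  dom <- solve_gem(spec_for("GEM", rr31 = 3, w = 1))
  expect_equal(dom$coefficients$beta[2], dom$coefficients$beta[3],
               tolerance = 1e-9)

  # a support straddling zero breaks monotonicity in the slope: rejected
  expect_error(solve_gem(spec_for("GEM", env = env_normal(0, 1))),
               "nonnegative exposure support")
})

test_that("solve_coefficients dispatches and always yields three pairs", {
  gm <- solve_coefficients(spec_for("GM"))
  expect_identical(gm$coefficients$beta, rep(0, 3))
  em <- solve_coefficients(spec_for("EM"))
  expect_length(unique(em$coefficients$alpha), 1L)
  expect_length(unique(em$coefficients$beta), 1L)
  for (model in c("GM", "EM", "GEM", "AM")) {
    sol <- solve_coefficients(spec_for(model))
    expect_length(sol$coefficients$alpha, 3L)
    expect_length(sol$coefficients$beta, 3L)
  }
  custom <- population_spec(
    100, hwe_genotype_freqs(0.5), env_uniform(0, 1), m = 0.1,
    model = "CUSTOM",
    coef_table = coef_table_from_coefficients(
      mlm_coefficients(c(-2, -2, -2), c(0, 0.1, 0.2))))
  expect_error(solve_coefficients(custom), "CUSTOM")
})

test_that("interaction-model constraints are validated pattern by pattern", {
  ok_gem <- mlm_coefficients(c(1, 1, 1), c(0.2, 0.5, 0.9))
  expect_true(validate_constraints(ok_gem, "GEM")$valid)
  bad_gem <- mlm_coefficients(c(1, 2, 3), c(0.1, 0.1, 0.1))
  v <- validate_constraints(bad_gem, "GEM")
  expect_false(v$valid)
  expect_match(v$violations, "alpha", all = FALSE)
  # ties are allowed by the inequalities
  expect_true(validate_constraints(mlm_coefficients(c(1, 1, 2), c(0, 0, 0)),
                                   "GM")$valid)
  # all violations are reported, not just the first
  both <- validate_constraints(mlm_coefficients(c(3, 2, 1), c(0.5, 0.2, 0)),
                               "GM")
  expect_length(both$violations, 2L)
  # EM needs a nonzero shared slope
  expect_false(validate_constraints(mlm_coefficients(c(1, 1, 1), c(0, 0, 0)),
                                    "EM")$valid)
})

test_that("solved coefficients conserve the disease frequency and the relative risks", {
  set.seed(77)
  for (k in 1:24) {
    spec <- random_population_spec()
    sol <- solve_coefficients(spec)
    env <- spec$env[[1]]
    fr <- spec$genotype_freqs[[1]]
    tr <- vapply(1:3, function(i) {
      total_risk(sol$coefficients$alpha[i], sol$coefficients$beta[i], env)
    }, numeric(1))
    expect_lt(abs(sum(fr * tr) - spec$m), 1e-8)
    expect_lt(abs(tr[3] / tr[1] - spec$rr31), 1e-6 * spec$rr31)
    expect_lt(abs(tr[2] / tr[1] - heterozygote_rr(spec$rr31, spec$w)), 1e-6)
    # discrete environments: check residuals via the exhaustive sum,
    # independently of the quadrature path
    if (env$kind == "discrete") {
      bf <- vapply(1:3, function(i) {
        brute_force_tr(sol$coefficients$alpha[i], sol$coefficients$beta[i], env)
      }, numeric(1))
      expect_lt(max(abs(bf - sol$target_tr)), 1e-8)
    }
  }
})

test_that("solvers are deterministic and exact in the point-mass limit", {
  spec <- spec_for("AM", env = env_discrete(c(0, 1, 2), c(0.4, 0.4, 0.2)))
  s1 <- solve_coefficients(spec)
  s2 <- solve_coefficients(spec)
  expect_identical(s1$coefficients, s2$coefficients)

  # point mass at 0: every solver returns alpha_i = logit(TR_i) exactly
  pm <- env_discrete(0, 1)
  gm <- solve_coefficients(spec_for("GM", env = pm))
  expect_identical(gm$coefficients$alpha, qlogis(gm$target_tr))
  em <- solve_coefficients(spec_for("EM", env = pm))
  expect_identical(em$coefficients$alpha, rep(qlogis(0.1), 3))
  am <- solve_coefficients(spec_for("AM", env = pm))
  expect_identical(am$coefficients$alpha, qlogis(am$target_tr))
})
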