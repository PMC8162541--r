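test_that("parameter validation enforces the domain", {
  expect_error(ddm_parameters(1, -1), "boundary")
  expect_error(ddm_parameters(1, 2, z_rel = 0), "starting point")
  expect_error(ddm_parameters(1, 2, z_rel = 1), "starting point")
  expect_error(ddm_parameters(1, 2, ndt_correct = -0.1), "non-decision")
  p <- ddm_parameters(1, 2, ndt_correct = 0.4, ndt_error = 0.2)
  expect_s3_class(p, "ddm_parameters")  # tau- < tau+ is allowed
  expect_identical(p$sigma, 1)
})

test_that("first-passage density integrates to the absorption probabilities", {
  # driftless centred process splits its mass evenly
  p0 <- ddm_parameters(0, 2)
  expect_equal(density_mass(p0, "upper"), 0.5, tolerance = 1e-4)
  for (p in param_grid()) {
    up <- density_mass(p, "upper")
    lo <- density_mass(p, "lower")
    expect_equal(up + lo, 1, tolerance = 1e-4)
    expect_equal(up, choice_probability(p, "upper"), tolerance = 1e-6)
  }
  expect_error(wfpt_density(-0.1, p0), "> 0")
  expect_error(wfpt_density(c(0.5, 0), p0), "> 0")
})

test_that("choice probability matches the closed form and its limits", {
  expect_equal(choice_probability(ddm_parameters(0, 2)), 0.5)
  expect_equal(choice_probability(ddm_parameters(50, 1)), 1,
               tolerance = 1e-9)
  # (1 - e^-4) / (1 - e^-8)
  expect_equal(choice_probability(ddm_parameters(2, 2)),
               (1 - exp(-4)) / (1 - exp(-8)), tolerance = 1e-12)
  expect_equal(choice_probability(ddm_parameters(2, 2)), 0.9820,
               tolerance = 1e-4)
  expect_equal(choice_probability(ddm_parameters(2, 2), "lower"),
               1 - choice_probability(ddm_parameters(2, 2)))
})

test_that("upper density under nu mirrors lower density under -nu at z = 0.5", {
  ts <- exp(seq(log(0.01), log(5), length.out = 50))
  for (v in c(0.5, 1.7, 3)) {
    up <- wfpt_density(ts, ddm_parameters(v, 1.8), "upper")
    lo <- wfpt_density(ts, ddm_parameters(-v, 1.8), "lower")
    expect_equal(up, lo, tolerance = 1e-10)
  }
})

test_that("density is numerically stable from 1 ms to 60 s", {
  p <- ddm_parameters(2, 2, ndt_correct = 0)
  d <- wfpt_density(c(0.001, 0.01, 1, 10, 60), p, "upper")
  expect_true(all(is.finite(d)) && all(d >= 0))
})

test_that("simulator reproduces driftless closed forms", {
  set.seed(42)
  p <- ddm_parameters(0, 2, ndt_correct = 0.4, ndt_error = 0.7)
  tr <- simulate_trials(p, 4e4)
  se <- sqrt(0.25 / 4e4)
  expect_lt(abs(mean(tr$correct) - 0.5), 3 * se)
  # driftless mean decision time from z = a/2 is z(a - z) = 1 s
  m_cor <- mean(tr$rt[tr$correct == 1])
  expect_lt(abs(m_cor - 1.4), 0.03)
  # at z = 0.5 both boundaries share the decision-time law, so the mean
  # RT difference is the non-decision difference
  m_err <- mean(tr$rt[tr$correct == 0])
  expect_lt(abs((m_err - m_cor) - 0.3), 0.04)
  expect_true(all(tr$rt[tr$correct == 1] > p$ndt_correct))
  expect_true(all(tr$rt[tr$correct == 0] > p$ndt_error))
})

test_that("simulated RT distributions agree with the density (KS)", {
  set.seed(7)
  for (p in param_grid()) {
    expect_lt(ks_sim_vs_density(p, n = 4e4), 0.01)
  }
})

test_that("simulator agrees with an Euler-Maruyama oracle", {
  set.seed(9)
  p <- ddm_parameters(1, 1.5, 0.5, 0, 0)
  e <- ddmlong:::euler_fpt_cpp(3e4, 1, 1.5, 0.5, 1e-4, 30)
  g <- ddmlong:::wfpt_cdf_grid(p, n_grid = 2048L)
  Fu <- approxfun(g$t, g$cdf_upper / g$p_upper, rule = 2)
  x <- sort(e$t[e$upper == 1])
  ks <- max(abs(Fu(x) - (seq_along(x) - 0.5) / length(x)))
  expect_lt(ks, 0.015)
  expect_lt(abs(mean(e$upper) - choice_probability(p)), 0.01)
})

test_that("condition effects are effect-coded and applied additively", {
  expect_error(condition_effects(drift_effects = rep(0.1, 10)),
               "sum to zero")
  expect_error(condition_effects(labels = letters[1:9]), "10")
  eff0 <- condition_effects()
  base <- ddm_parameters(2, 2, ndt_correct = 0.4)
  same <- apply_condition_effects(base, eff0, eff0$labels[1])
  expect_equal(same, base)

  labs <- default_condition_labels()
  de <- c(0.3, rep(-0.3 / 9, 9))
  eff <- condition_effects(labs, drift_effects = de)
  out <- apply_condition_effects(base, eff, labs[1])
  expect_equal(out$drift, 2.3)
  expect_equal(out$ndt_correct, base$ndt_correct)
  # the condition-specific means average back to the intercept
  all_nu <- vapply(labs, function(l)
    apply_condition_effects(base, eff, l)$drift, numeric(1))
  expect_equal(mean(all_nu), base$drift)
  expect_error(apply_condition_effects(base, eff, "nope"), "unknown")
  bad <- condition_effects(labs, boundary_effects = c(-2.1, rep(2.1 / 9, 9)))
  expect_error(apply_condition_effects(base, bad, labs[1]), "non-positive")
})
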