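# simulate a wide person x occasion matrix directly from growth
# parameters (the generator's trajectory draw, without the trial layer)
sim_wide <- function(gp, n, seed) {
  set.seed(seed)
  g <- ddmlong:::draw_growth_values(gp, n)
  g$values
}

nu_gp <- function() growth_params(2.104, 0.164, 0.112, 0.026, 0,
                                  c(0, 1, 1.142, 1.297),
                                  c(0.020, 0.036, 0.060, 0.082))
a_gp <- function() growth_params(2.053, 0.274, -0.123, 0, 0,
                                 c(0, 1, 1.233, 1.334),
                                 c(0.060, 0.020, 0.036, 0.045))
tau_gp <- function() growth_params(0.436, 0.006, -0.010, 0, 0,
                                   c(0, 1, -0.358, 0.509),
                                   c(0.001, 1e-4, 0.001, 0.002))

test_that("growth model recovers drift-rate generating values at N = 300", {
  Y <- sim_wide(nu_gp(), 300, seed = 21)
  fit <- suppressWarnings(
    fit_growth_curve(Y, n_chains = 3, n_iter = 6000, n_burnin = 3000,
                     seed = 5))
  s <- fit$summary
  covers <- function(nm, val) {
    s[nm, "ci_lower"] <= val && val <= s[nm, "ci_upper"]
  }
  expect_true(covers("mu_i", 2.104))
  expect_true(covers("mu_s", 0.112))
  expect_true(covers("l3", 1.142))
  expect_true(covers("l4", 1.297))
  # a real slope variance must not be fixed away
  expect_false(fit$fixed[["var_s"]])
  expect_true(fit$fixed[["cov_is"]])  # generating covariance is zero
  expect_lt(max(fit$rhat[c("mu_i", "mu_s", "l3", "l4")]), 1.02)
  # indices near their ceiling for a well-specified model
  expect_gt(fit$fit_indices[["bCFI"]], 0.99)
  expect_gt(fit$fit_indices[["bGammaHat"]], 0.99)
})

test_that("zero slope variance triggers the fixing rule (boundary, non-decision)", {
  for (cfg in list(list(gp = a_gp(), seed = 22),
                   list(gp = tau_gp(), seed = 23))) {
    Y <- sim_wide(cfg$gp, 300, seed = cfg$seed)
    fit <- suppressWarnings(
      fit_growth_curve(Y, n_chains = 2, n_iter = 4000, n_burnin = 2000,
                       seed = 6))
    expect_true(fit$fixed[["var_s"]])
    expect_true(fit$fixed[["cov_is"]])
    s <- fit$summary
    expect_true(s["mu_i", "ci_lower"] <= cfg$gp$mean_i &&
                  cfg$gp$mean_i <= s["mu_i", "ci_upper"])
  }
})

test_that("null slope generation: mean covers zero and variance is fixed", {
  gp <- growth_params(2, 0.2, 0, 0, 0, c(0, 1, 1.1, 1.2),
                      rep(0.03, 4))
  Y <- sim_wide(gp, 250, seed = 24)
  fit <- suppressWarnings(
    fit_growth_curve(Y, n_chains = 2, n_iter = 4000, n_burnin = 2000,
                     seed = 7))
  s <- fit$summary
  expect_true(s["mu_s", "ci_lower"] <= 0 && 0 <= s["mu_s", "ci_upper"])
  expect_true(fit$fixed[["var_s"]])
})

test_that("credible intervals cover generating values across replicates", {
  n_rep <- 20L
  truth <- c(mu_i = 2.104, mu_s = 0.112, l3 = 1.142, l4 = 1.297)
  hits <- matrix(0L, n_rep, 4, dimnames = list(NULL, names(truth)))
  for (r in seq_len(n_rep)) {
    Y <- sim_wide(nu_gp(), 300, seed = 100 + r)
    fit <- suppressWarnings(
      fit_growth_curve(Y, n_chains = 2, n_iter = 2500, n_burnin = 1250,
                       seed = 40 + r))
    s <- fit$summary
    for (nm in names(truth)) {
      hits[r, nm] <- s[nm, "ci_lower"] <= truth[nm] &&
        truth[nm] <= s[nm, "ci_upper"]
    }
  }
  # each parameter's 95% interval covers its generating value in at
  # least 90% of replicates
  expect_true(all(colMeans(hits) >= 0.9))
})

test_that("missing occasions are handled by marginalization and listwise switch", {
  Y <- sim_wide(nu_gp(), 320, seed = 26)
  drop <- sample(seq_len(320), 60)
  Y[drop[1:30], 4] <- NA
  Y[drop[31:60], 3:4] <- NA
  fiml <- suppressWarnings(
    fit_growth_curve(Y, n_chains = 2, n_iter = 3000, n_burnin = 1500,
                     seed = 8))
  lw <- suppressWarnings(
    fit_growth_curve(Y, n_chains = 2, n_iter = 3000, n_burnin = 1500,
                     seed = 8, missing = "listwise"))
  expect_equal(fiml$n, 320L)
  expect_equal(lw$n, 260L)
  expect_lt(abs(fiml$summary["mu_i", "estimate"] -
                  lw$summary["mu_i", "estimate"]), 0.1)
  expect_error(fit_growth_curve(Y[1:30, ]), "at least 50")
})
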