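mk_medians <- function(n = 30, tps = 1:2, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(tps, function(tp) {
    data.frame(participant_id = sprintf("P%02d", seq_len(n)),
               time_point = tp,
               nu = rnorm(n, 2, 0.4), a = rnorm(n, 2, 0.5),
               tau_plus = rnorm(n, 0.43, 0.08))
  }))
}

test_that("z-standardization is exact, per time point, and location invariant", {
  med <- mk_medians()
  z <- standardize_profiles(med)
  for (tp in 1:2) {
    for (p in c("nu", "a", "tau_plus")) {
      col <- z[[p]][z$time_point == tp]
      expect_lt(abs(mean(col)), 1e-12)
      expect_lt(abs(sd(col) - 1), 1e-12)
    }
  }
  shifted <- med
  shifted$nu[shifted$time_point == 1] <-
    shifted$nu[shifted$time_point == 1] + 5
  z2 <- standardize_profiles(shifted)
  expect_equal(z2$nu, z$nu, tolerance = 1e-12)

  # a person at the 97.7th percentile of a normal column scores z ~ +2
  med2 <- mk_medians(n = 2001, seed = 3)
  med2$nu[med2$time_point == 1] <- qnorm(seq(0.0005, 0.9995,
                                             length.out = 2001), 2, 0.4)
  z3 <- standardize_profiles(med2)
  i977 <- which.min(abs(seq(0.0005, 0.9995, length.out = 2001) - 0.977))
  expect_equal(z3$nu[z3$time_point == 1][i977], 2, tolerance = 0.05)

  zero_var <- med
  zero_var$a[zero_var$time_point == 2] <- 1.7
  expect_error(standardize_profiles(zero_var), "zero variance for a")

  zp <- standardize_profiles(med, scope = "pooled")
  expect_lt(abs(mean(zp$nu)), 1e-12)
})

test_that("q correlations reproduce hand-computed 3-point profiles", {
  z <- rbind(
    data.frame(participant_id = c("A", "B", "C"), time_point = 1,
               nu = c(1, 1, 1), a = c(0, 0, -0.5), tau_plus = c(-1, -1, 0.2)),
    data.frame(participant_id = c("A", "B", "C"), time_point = 2,
               nu = c(1, -1, 0.8), a = c(0, 0, -0.7),
               tau_plus = c(-1, 1, 0.1)))
  q <- q_profile_correlations(z, 1, 2)
  rec <- q$records
  expect_equal(rec$q[rec$participant_id == "A"], 1)
  expect_equal(rec$q[rec$participant_id == "B"], -1)
  # (1, -0.5, 0.2) vs (0.8, -0.7, 0.1), hand-computed Pearson
  z2 <- z
  z2[z2$participant_id == "C" & z2$time_point == 1,
     c("nu", "a", "tau_plus")] <- c(1, -0.5, 0.2)
  z2[z2$participant_id == "C" & z2$time_point == 2,
     c("nu", "a", "tau_plus")] <- c(0.8, -0.7, 0.1)
  q2 <- q_profile_correlations(z2, 1, 2)
  expect_equal(q2$records$q[q2$records$participant_id == "C"], 0.99699,
               tolerance = 1e-4)
})

test_that("q correlations: rescaling invariance, zero-variance and missing handling", {
  set.seed(4)
  z <- mk_medians(20)
  q1 <- q_profile_correlations(z, 1, 2)
  z_scaled <- z
  z_scaled[, c("nu", "a", "tau_plus")] <-
    z_scaled[, c("nu", "a", "tau_plus")] * 3
  q2 <- q_profile_correlations(z_scaled, 1, 2)
  expect_equal(q1$records$q, q2$records$q, tolerance = 1e-12)

  z$nu[z$participant_id == "P01"] <- NA
  z[z$participant_id == "P02", c("nu", "a", "tau_plus")] <- 0.5
  q3 <- q_profile_correlations(z, 1, 2)
  expect_true(is.na(q3$records$q[q3$records$participant_id == "P01"]))
  expect_true(is.na(q3$records$q[q3$records$participant_id == "P02"]))
  expect_equal(q3$summary$n_zero_variance, 1L)
  expect_equal(q3$summary$n, 18L)

  qs <- q_profile_summary(mk_medians(15, tps = 1:4))
  expect_equal(nrow(qs), 6L)
})

test_that("Bayes-factor t-test agrees with a noncentral-t quadrature oracle", {
  set.seed(5)
  x <- rnorm(40, 0.5); y <- rnorm(55)
  res <- dropout_bayes_t_test(x, y)
  # oracle: BF = int p(t | delta) Cauchy(delta) ddelta / p(t | 0) with
  # p(t | delta) the noncentral-t density of the observed statistic
  neff <- 40 * 55 / 95
  df <- 93
  marg <- suppressWarnings(integrate(function(d) {
    dt(res$t, df, ncp = d * sqrt(neff)) * dcauchy(d, 0, sqrt(2) / 2)
  }, -Inf, Inf, rel.tol = 1e-8)$value)
  bf_ref <- marg / dt(res$t, df)
  expect_equal(res$bf10, bf_ref, tolerance = 0.01)
})

test_that("Bayes-factor t-test: null and strong-effect behaviour", {
  set.seed(6)
  bfs <- replicate(10, dropout_bayes_t_test(rnorm(150), rnorm(150))$bf10)
  expect_gt(mean(bfs < 1), 0.5)
  big <- dropout_bayes_t_test(rnorm(100, 1.5), rnorm(100))
  expect_gt(big$bf10, 100)
  expect_error(dropout_bayes_t_test(rep(1, 5), rep(1, 5)), "pooled variance")
  expect_error(dropout_bayes_t_test(1, rnorm(5)), "n >= 2")
})

test_that("parameter-dependent dropout elevates the non-decision-time test", {
  set.seed(7)
  cohort <- cohort_config(subgroup_sizes = c(150, 100, 50, 50, 32),
                          retention = c(382, 250, 220, 220),
                          dropout = "parameter")
  tr <- draw_person_trajectories(longitudinal_model(), cohort)$trajectories
  t1 <- tr[tr$time_point == 1, ]
  miss <- unique(tr$participant_id[tr$time_point > 1 & !tr$observed])
  x <- t1$tau_plus[t1$participant_id %in% miss]
  y <- t1$tau_plus[!t1$participant_id %in% miss]
  expect_gt(mean(x), mean(y))  # droppers carry higher values
  res <- dropout_bayes_t_test(x, y)
  expect_gt(res$bf10, 1)
})
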