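# independent reference implementation of split R-hat on rank-normalized
# draws, written directly from the defining formula
ref_rhat <- function(mat) {
  h <- nrow(mat) %/% 2
  sp <- cbind(mat[1:h, ], mat[(nrow(mat) - h + 1):nrow(mat), ])
  S <- length(sp)
  z <- matrix(qnorm((rank(sp, ties.method = "average") - 3 / 8) /
                      (S + 1 / 4)), nrow(sp), ncol(sp))
  n <- nrow(z); m <- ncol(z)
  B <- n / (m - 1) * sum((colMeans(z) - mean(z))^2)
  W <- mean(apply(z, 2, var))
  sqrt(((n - 1) / n * W + B / n) / W)
}

test_that("R-hat conventions and null/alternative behaviour", {
  expect_equal(rhat(matrix(5, 20, 4)), 1)  # zero-variance convention
  set.seed(1)
  iid <- matrix(rnorm(20000), 5000, 4)
  expect_lt(rhat(iid), 1.005)
  shifted <- cbind(rnorm(500), rnorm(500) + 5)
  expect_gt(rhat(shifted), 1.5)
  expect_error(rhat(rnorm(100)), "2 chains")
  expect_error(rhat(matrix(rnorm(4), 2, 2)), "4 iterations")
})

test_that("R-hat matches the explicit formula on a small case", {
  set.seed(2)
  toy <- matrix(rnorm(20, mean = rep(c(0, 2), each = 10)), 10, 2)
  expect_equal(rhat(toy), ref_rhat(toy), tolerance = 1e-12)
})

test_that("bulk ESS tracks independence and AR(1) closed forms", {
  set.seed(3)
  iid <- matrix(rnorm(20000), 5000, 4)
  expect_lt(abs(bulk_ess(iid) - 20000) / 20000, 0.10)
  # AR(1) with phi = 0.9: ESS ~ N (1 - phi) / (1 + phi) = 526
  phi <- 0.9
  x <- numeric(10000)
  for (i in 2:10000) x[i] <- phi * x[i - 1] + rnorm(1)
  e <- bulk_ess(x)
  expect_lt(abs(e - 526) / 526, 0.20)
  expect_equal(bulk_ess(matrix(1, 100, 2)), 0)
})

test_that("diagnostics are invariant under affine transformation", {
  set.seed(4)
  x <- matrix(rnorm(2000), 500, 4)
  expect_equal(rhat(2 * x + 1), rhat(x))
  expect_equal(bulk_ess(2 * x + 1), bulk_ess(x))
})

test_that("joint exclusion rule drops whole person vectors and is monotone", {
  med <- data.frame(participant_id = sprintf("P%d", 1:100),
                    nu = rnorm(100, 2), a = rnorm(100, 2),
                    tau_plus = rnorm(100, 0.4, 0.02),
                    tau_minus = rnorm(100, 0.7, 0.02))
  diag <- expand.grid(participant_id = med$participant_id,
                      parameter = c("nu", "a", "tau_plus", "tau_minus"),
                      stringsAsFactors = FALSE)
  diag$rhat <- 1.0
  diag$ess <- 1000
  diag$pass <- TRUE
  # P1 fails ESS on tau_minus only
  sel <- diag$participant_id == "P1" & diag$parameter == "tau_minus"
  diag$pass[sel] <- FALSE
  res <- apply_exclusion_rules(med, diag)
  row <- res$medians[res$medians$participant_id == "P1", ]
  expect_true(all(is.na(row[, c("nu", "a", "tau_plus", "tau_minus")])))
  expect_equal(res$excluded, "P1")

  # 7 persons with any failure -> 7% exclusion fraction
  diag2 <- diag
  sel7 <- diag2$participant_id %in% sprintf("P%d", 1:7) &
    diag2$parameter == "a"
  diag2$pass[sel7] <- FALSE
  res7 <- apply_exclusion_rules(med, diag2)
  expect_equal(res7$fraction, 0.07)
  # monotone: adding a failure can never un-exclude
  diag3 <- diag2
  diag3$pass[diag3$participant_id == "P9"] <- FALSE
  res9 <- apply_exclusion_rules(med, diag3)
  expect_true(all(res7$excluded %in% res9$excluded))

  # all passing -> all retained
  all_pass <- diag
  all_pass$pass <- TRUE
  expect_length(apply_exclusion_rules(med, all_pass)$excluded, 0)
})

test_that("posterior predictive check is self-consistent and applies the error-trial rule", {
  dat <- small_cohort_t1(n_participants = 12, trials_per_block = 25,
                         seed = 19)
  m <- build_model(dat$trials)
  fit <- run_mcmc(m, n_chains = 2, n_iter = 500, n_burnin = 200, seed = 2)
  expect_error(posterior_predictive_check(fit, dat$trials, n_draws = 10000),
               "exceeds")
  set.seed(30)
  ppc <- posterior_predictive_check(fit, dat$trials, n_draws = 40)
  q50 <- ppc[ppc$statistic == "rt_correct_q50", ]
  expect_gte(cor(q50$observed, q50$predicted), 0.95)
  er <- ppc[ppc$statistic == "error_rate", ]
  expect_equal(nrow(er), length(fit$person_ids))
  expect_lt(mean(abs(er$observed - er$predicted)), 0.03)
  # persons with <= 10 observed errors carry no error-RT rows
  nerr <- tapply(1 - dat$trials$correct, dat$trials$participant_id, sum)
  few <- names(nerr)[nerr <= 10]
  if (length(few)) {
    expect_false(any(ppc$participant_id %in% few &
                       grepl("^rt_error", ppc$statistic)))
  }
  # predicted error rate agrees with the closed-form choice probability
  # under the person's posterior-median parameters and condition mix
  med <- extract_person_medians(fit)
  id <- fit$person_ids[1]
  eff <- dat$cohort$effects
  pm <- med[med$participant_id == id, ]
  pr_err <- mean(vapply(eff$labels, function(l) {
    p <- apply_condition_effects(
      ddm_parameters(pm$nu, pm$a, 0.5, pm$tau_plus, pm$tau_minus), eff, l)
    choice_probability(p, "lower")
  }, numeric(1)))
  got <- er$predicted[er$participant_id == id]
  expect_lt(abs(got - pr_err), 0.03)
})
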