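mk_fit_trials <- function(n_person = 3, n_per_cond = 6, seed = 2,
                          nu = 2, a = 2, tp = 0.4, tm = 0.7) {
  set.seed(seed)
  labs <- default_condition_labels()
  out <- list()
  for (p in seq_len(n_person)) {
    for (ci in seq_along(labs)) {
      tr <- simulate_trials(ddm_parameters(nu, a, 0.5, tp, tm), n_per_cond)
      tc <- strsplit(labs[ci], ":")[[1]]
      out[[length(out) + 1]] <- data.frame(
        participant_id = sprintf("S%02d", p), trait = tc[1],
        congruency = tc[2], correct = tr$correct, rt_s = tr$rt)
    }
  }
  do.call(rbind, out)
}

test_that("model structure: 22 free person parameters, trial/person counts", {
  spec <- ddm_model_spec()
  expect_equal(spec$n_person_params, 22L)
  trials <- mk_fit_trials(n_person = 10)
  m <- build_model(trials, spec)
  expect_equal(length(m$person_ids) * spec$n_person_params, 220L)
  expect_output(print(m), "220")
})

test_that("build_model enforces its contracts", {
  trials <- mk_fit_trials(n_person = 3)
  # participant with too few retained trials is dropped with a warning
  few <- trials[trials$participant_id != "S01" |
                  seq_len(nrow(trials)) <= 10, ]
  expect_warning(m <- build_model(few), "fewer than 20")
  expect_equal(length(m$person_ids), 2L)

  bad <- trials
  bad$trait[1] <- "patience"
  expect_error(build_model(bad), "unknown condition")

  expect_error(build_model(trials[trials$participant_id == "S01", ]),
               "at least 2")

  # an all-correct participant is allowed
  ac <- trials
  ac$correct[ac$participant_id == "S01"] <- 1L
  expect_s3_class(build_model(ac), "ddm_model")
})

test_that("joint log density equals a hand-assembled term-by-term sum", {
  labs <- default_condition_labels()
  trials <- data.frame(
    participant_id = c("A", "A", "A", "B", "B"),
    condition = labs[c(1, 2, 10, 1, 5)],
    correct = c(1L, 1L, 0L, 1L, 1L),
    rt_s = c(0.62, 0.55, 1.10, 0.80, 0.71))
  spec <- ddm_model_spec(min_trials = 1L)
  m <- build_model(trials, spec)
  state <- list(nu = c(2.1, 1.8), a = c(1.9, 2.2),
                tau_plus = c(0.40, 0.42), tau_minus = c(0.70, 0.72),
                nu_eff = matrix(seq(-0.2, 0.2, length.out = 18), 2, 9),
                a_eff = matrix(0.01, 2, 9),
                delta_nu = rep(0.05, 9), delta_a = rep(0, 9),
                sigma_nu_eff = 0.2, sigma_a_eff = 0.1,
                mu_nu = 2, sigma_nu = 0.5, mu_a = 2, sigma_a = 0.5,
                mu_tau_plus = 0.4, sigma_tau_plus = 0.1,
                mu_tau_minus = 0.7, sigma_tau_minus = 0.15)

  # oracle: assemble the sum directly from wfpt_density and the priors
  eff10 <- function(m) cbind(m, -rowSums(m))
  ne <- eff10(state$nu_eff); ae <- eff10(state$a_eff)
  ll <- 0
  for (i in seq_len(nrow(trials))) {
    p <- match(trials$participant_id[i], m$person_ids)
    ci <- match(trials$condition[i], labs)
    pars <- ddm_parameters(state$nu[p] + ne[p, ci], state$a[p] + ae[p, ci],
                           0.5, state$tau_plus[p], state$tau_minus[p])
    bound <- if (trials$correct[i] == 1) "upper" else "lower"
    tau <- if (trials$correct[i] == 1) state$tau_plus[p] else
      state$tau_minus[p]
    ll <- ll + wfpt_density(trials$rt_s[i] - tau, pars, bound, log = TRUE)
  }
  pr <- m$priors
  lhn <- function(x, s) log(2) + dnorm(x, 0, s, log = TRUE)
  lp <- sum(dnorm(state$nu, 2, 0.5, TRUE)) +
    sum(dnorm(state$a, 2, 0.5, TRUE)) +
    sum(dnorm(state$tau_plus, 0.4, 0.1, TRUE)) +
    sum(dnorm(state$tau_minus, 0.7, 0.15, TRUE)) +
    sum(dnorm(state$nu_eff, 0.05, 0.2, TRUE)) +
    sum(dnorm(state$a_eff, 0, 0.1, TRUE)) +
    dnorm(2, pr$mu_nu_mean, pr$mu_nu_sd, TRUE) +
    dnorm(2, pr$mu_a_mean, pr$mu_a_sd, TRUE) +
    dnorm(0.4, pr$mu_tau_mean, pr$mu_tau_sd, TRUE) +
    dnorm(0.7, pr$mu_tau_mean, pr$mu_tau_sd, TRUE) +
    sum(dnorm(rep(0.05, 9), 0, pr$delta_nu_sd, TRUE)) +
    sum(dnorm(rep(0, 9), 0, pr$delta_a_sd, TRUE)) +
    lhn(0.5, pr$sigma_nu_scale) + lhn(0.5, pr$sigma_a_scale) +
    lhn(0.1, pr$sigma_tau_scale) + lhn(0.15, pr$sigma_tau_scale) +
    lhn(0.2, pr$sigma_nu_eff_scale) + lhn(0.1, pr$sigma_a_eff_scale)
  expect_equal(model_log_density(m, state), ll + lp, tolerance = 1e-8)
})

test_that("run_mcmc keeps the contracted draw geometry and is deterministic", {
  trials <- mk_fit_trials(n_person = 2, n_per_cond = 2, seed = 4)
  m <- build_model(trials, ddm_model_spec(min_trials = 1L))
  fit <- run_mcmc(m, n_chains = 2, n_iter = 150, n_burnin = 50, seed = 7)
  expect_equal(dim(fit$draws)[1:2], c(100L, 2L))
  expect_true(all(is.finite(fit$draws)))
  expect_equal(fit$n_burnin, 50)
  expect_equal(fit$seed, 7)
  fit2 <- run_mcmc(m, n_chains = 2, n_iter = 150, n_burnin = 50, seed = 7)
  expect_identical(fit$draws, fit2$draws)
  fit3 <- run_mcmc(m, n_chains = 2, n_iter = 150, n_burnin = 50, seed = 8)
  expect_false(identical(fit$draws, fit3$draws))
})

test_that("posterior recovers known generating parameters (small fit)", {
  trials <- mk_fit_trials(n_person = 3, n_per_cond = 30, seed = 5,
                          nu = 2.0, a = 1.8, tp = 0.40, tm = 0.70)
  m <- build_model(trials)
  fit <- run_mcmc(m, n_chains = 2, n_iter = 900, n_burnin = 400, seed = 3)
  for (spec in list(c("nu[S01]", 2.0), c("a[S01]", 1.8),
                    c("tau_plus[S01]", 0.40))) {
    d <- draws_of(fit, spec[1])
    expect_lt(abs(mean(d) - as.numeric(spec[2])), 3 * sd(d) + 0.05)
  }
  # shrinkage: tau_minus of a near-errorless person tracks the hierarchy
  med <- extract_person_medians(fit)
  expect_true(all(is.finite(med$tau_minus)))
})

test_that("person medians are medians and missing persons yield NA rows", {
  trials <- mk_fit_trials(n_person = 2, n_per_cond = 2, seed = 4)
  m <- build_model(trials, ddm_model_spec(min_trials = 1L))
  fit <- run_mcmc(m, n_chains = 2, n_iter = 120, n_burnin = 20, seed = 7)
  med <- extract_person_medians(fit, all_ids = c("S01", "S02", "ZZZ"))
  expect_equal(nrow(med), 3L)
  expect_true(is.na(med$nu[med$participant_id == "ZZZ"]))
  expect_equal(med$nu[1], median(draws_of(fit, "nu[S01]")))
  expect_named(med, c("participant_id", "nu", "a", "tau_plus", "tau_minus"))
})
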