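test_that("degenerate generator yields deterministic trajectories", {
  set.seed(1)
  gp <- growth_params(2, 0, 0.5, 0, 0, loadings = c(0, 1, 1.5, 2))
  model <- longitudinal_model(nu = gp,
                              a = growth_params(2, 0, 0, 0),
                              tau = growth_params(0.4, 0, 0, 0))
  cohort <- tiny_cohort()
  drawn <- draw_person_trajectories(model, cohort)
  tr <- drawn$trajectories
  for (t in 1:4) {
    expect_equal(unique(tr$nu[tr$time_point == t]), 2 + 0.5 * gp$loadings[t])
  }
  expect_equal(unique(tr$tau_minus - tr$tau_plus), 0.3)
})

test_that("generated parameter means and stability follow the growth model", {
  set.seed(21)
  cohort <- cohort_config(subgroup_sizes = c(4000, 3000, 1000, 1000, 1000),
                          retention = rep(10000, 4))
  model <- longitudinal_model()
  drawn <- draw_person_trajectories(model, cohort)
  tr <- drawn$trajectories
  # occasion means mu_I + mu_S * lambda_t within 3 standard errors
  for (fam in c("nu", "a", "tau_plus")) {
    gp <- model[[if (fam == "tau_plus") "tau" else fam]]
    for (t in 1:4) {
      x <- tr[[fam]][tr$time_point == t]
      se <- sd(x) / sqrt(length(x))
      expect_lt(abs(mean(x) - (gp$mean_i + gp$mean_s * gp$loadings[t])),
                3 * se + 1e-8)
    }
  }
  # drift at occasion 2: 2.104 + 0.112
  x2 <- tr$nu[tr$time_point == 2]
  expect_lt(abs(mean(x2) - 2.216), 3 * sd(x2) / sqrt(length(x2)))
  # occasion 1-2 correlation of true drift matches the
  # variance-component closed form
  w <- reshape(tr[, c("participant_id", "time_point", "nu")],
               direction = "wide", idvar = "participant_id",
               timevar = "time_point")
  r12 <- cor(w[["nu.1"]], w[["nu.2"]])
  expect_equal(trajectory_correlation(model$nu, 1, 2), 0.804,
               tolerance = 5e-4)
  expect_lt(abs(r12 - trajectory_correlation(model$nu, 1, 2)),
            3 / sqrt(nrow(w)))
  # truncation respected
  expect_true(all(tr$a > 0.2) && all(tr$tau_plus > 0.05))
})

test_that("dropout mask reproduces the retention counts exactly", {
  set.seed(3)
  cohort <- cohort_config(subgroup_sizes = c(40, 30, 10, 15, 5),
                          retention = c(100, 80, 60, 60))
  drawn <- draw_person_trajectories(longitudinal_model(), cohort)
  tr <- drawn$trajectories
  counts <- tapply(tr$observed, tr$time_point, sum)
  expect_equal(as.vector(counts), c(100, 80, 60, 60))
  # monotone: once missing, missing at all later occasions
  w <- tapply(tr$observed, list(tr$participant_id, tr$time_point), identity)
  expect_true(all(apply(w, 1, function(o) all(diff(as.integer(o)) <= 0))))
})

test_that("trial generation follows the 10-block, 600-trial design", {
  set.seed(5)
  cohort <- tiny_cohort(n_per_block = 60L)
  drawn <- draw_person_trajectories(longitudinal_model(), cohort)
  one <- drawn$trajectories[drawn$trajectories$participant_id == "P001" &
                              drawn$trajectories$time_point == 1, ]
  trials <- generate_trials(one, cohort)
  expect_equal(nrow(trials), 600L)
  expect_equal(sum(trials$warmup_flag), 10L)
  expect_equal(as.vector(tapply(trials$warmup_flag, trials$block_index, sum)),
               rep(1L, 10))
  expect_equal(length(unique(paste(trials$trait, trials$congruency))), 10L)
  # every RT exceeds the applicable non-decision time
  tau <- ifelse(trials$correct == 1, one$tau_plus, one$tau_minus)
  expect_true(all(trials$rt_s > tau))
})

test_that("simulated accuracy matches the closed-form choice probability", {
  set.seed(6)
  traj <- data.frame(participant_id = "P001", subgroup = 1,
                     age_group = "young", age = 22, time_point = 1,
                     month = 0, observed = TRUE, nu = 2.09, a = 2.04,
                     tau_plus = 0.43, tau_minus = 0.73)
  cohort <- cohort_config(subgroup_sizes = c(1, 0, 0, 0, 0),
                          retention = rep(1, 4),
                          effects = condition_effects())  # zero effects
  trials <- generate_trials(traj, cohort)
  p_expect <- choice_probability(ddm_parameters(2.09, 2.04))
  se <- sqrt(p_expect * (1 - p_expect) / nrow(trials))
  expect_lt(abs(mean(trials$correct) - p_expect), 4 * se)
})

test_that("regeneration with the same seed is bit-for-bit identical", {
  gen <- function() {
    set.seed(99)
    drawn <- draw_person_trajectories(longitudinal_model(), tiny_cohort())
    generate_trials(drawn$trajectories, tiny_cohort())
  }
  expect_identical(gen(), gen())
})

test_that("artifact injection is exact bookkeeping", {
  set.seed(12)
  drawn <- draw_person_trajectories(longitudinal_model(), tiny_cohort())
  trials <- generate_trials(
    drawn$trajectories[drawn$trajectories$time_point == 1, ], tiny_cohort())
  same <- inject_artifacts(trials)
  expect_identical(same$trials, trials)
  expect_equal(unname(same$counts), c(0L, 0L, 0L, 0L))

  inj <- inject_artifacts(trials, fast_rate = 0.01, slow_rate = 0.02,
                          nonrecorded_rate = 0.05)
  expect_equal(unname(inj$counts[["fast"]]), round(0.01 * nrow(trials)))
  expect_equal(sum(inj$trials$rt_s < 0.3 & inj$trials$recorded_flag) -
                 sum(trials$rt_s < 0.3 & trials$recorded_flag) >= 0, TRUE)
  expect_equal(sum(!inj$trials$recorded_flag), inj$counts[["nonrecorded"]])
  expect_error(inject_artifacts(trials, fast_rate = 0.6), "0.5")
})

test_that("trial CSV round-trips through the documented dialect", {
  set.seed(31)
  drawn <- draw_person_trajectories(longitudinal_model(), tiny_cohort())
  trials <- generate_trials(
    drawn$trajectories[drawn$trajectories$time_point == 1, ], tiny_cohort())
  f <- tempfile(fileext = ".csv")
  write_trials(trials, f)
  back <- read_trials(f)
  expect_equal(back$rt_s, round(trials$rt_s, 6))
  expect_identical(back$participant_id, trials$participant_id)
  expect_identical(back$warmup_flag, trials$warmup_flag)
  unlink(f)
})
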