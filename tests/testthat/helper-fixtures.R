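# shared fixtures: small cohorts and parameter grids used across tests

param_grid <- function() {
  list(
    ddm_parameters(1.0, 1.5, 0.5, 0.3, 0.5),
    ddm_parameters(2.0, 2.0, 0.5, 0.4, 0.7),
    ddm_parameters(0.5, 1.0, 0.3, 0.2, 0.2),
    ddm_parameters(-1.0, 2.5, 0.5, 0.35, 0.35),
    ddm_parameters(3.0, 1.2, 0.7, 0.25, 0.4))
}

tiny_cohort <- function(n_per_block = 10L) {
  cohort_config(subgroup_sizes = c(4, 3, 2, 2, 1),
                retention = c(12, 11, 10, 10),
                trials_per_block = n_per_block)
}

small_cohort_t1 <- function(n_participants = 20, trials_per_block = 60,
                            seed = 11) {
  set.seed(seed)
  sizes <- c(n_participants - 10, 5, 2, 2, 1)
  cohort <- cohort_config(subgroup_sizes = sizes,
                          retention = rep(n_participants, 4),
                          trials_per_block = trials_per_block)
  drawn <- draw_person_trajectories(longitudinal_model(), cohort)
  t1 <- drawn$trajectories[drawn$trajectories$time_point == 1, ]
  trials <- generate_trials(t1, cohort)
  list(truth = t1, trials = trials, cohort = cohort)
}

# numeric integral of the first-passage density over (0, Inf)
density_mass <- function(params, boundary) {
  integrate(function(t) wfpt_density(t, params, boundary),
            1e-6, Inf, rel.tol = 1e-9)$value
}

# empirical KS distance between simulated RTs and the density-implied
# conditional CDF, on the boundary holding the larger share of the mass
ks_sim_vs_density <- function(params, n = 5e4) {
  tr <- simulate_trials(params, n)
  g <- ddmlong:::wfpt_cdf_grid(params, n_grid = 2048L)
  use_upper <- choice_probability(params, "upper") >= 0.5
  if (use_upper) {
    Fu <- approxfun(g$t + params$ndt_correct, g$cdf_upper / g$p_upper,
                    rule = 2)
    x <- sort(tr$rt[tr$correct == 1])
  } else {
    Fu <- approxfun(g$t + params$ndt_error, g$cdf_lower / g$p_lower,
                    rule = 2)
    x <- sort(tr$rt[tr$correct == 0])
  }
  max(abs(Fu(x) - (seq_along(x) - 0.5) / length(x)))
}
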