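# ddmlong

Longitudinal stability and change in diffusion model parameters.

`ddmlong` is for researchers who use the Wiener diffusion model to
measure individual differences in two-choice tasks and want to know
whether its parameters behave like traits over time. The package covers
the full analysis chain for a four-occasion (months 0/6/12/24),
five-subgroup cohort performing Implicit Association Tests: a synthetic
cohort generator with known person-level growth trajectories,
trial-level preprocessing, per-occasion hierarchical Bayesian estimation
of the diffusion model, convergence-gated extraction of person-level
posterior medians, and four stability analyses.

## The model

A decision is a Wiener process with drift $\nu$ (speed of information
uptake) between boundaries $0$ and $a$ (decision caution), starting at
$z = 0.5\,a$, with unit diffusion coefficient. The response time adds a
non-decision component, split by outcome: $\tau^+$ on correct responses
and $\tau^-$ on errors, the latter absorbing the time to correct the
response in tasks that record only the corrected answer. Task conditions
(5 traits × congruent/incongruent) shift $\nu$ and $a$ through
effect-coded (sum-to-zero) condition effects, so person-level intercepts
are grand means across conditions. Inter-trial variabilities are fixed
at zero and the starting point at one half.

Person trajectories follow a latent growth model: the value of a
parameter at occasion $t$ is $I + S\lambda_t + e_t$ with loadings fixed
at 0 and 1 for the first two occasions and free afterwards. The four
stability analyses are rank-order stability (Bayesian correlations,
uniform prior, Savage–Dickey Bayes factors), mean-level change (95%
highest-density-interval comparison of group-level posteriors),
individual differences in change (Bayesian latent growth curves with
covariance/slope-variance fixing rules and bCFI/bGammaHat fit indices),
and profile stability (within-person q correlations of z-standardized
parameter profiles).

## Worked example

```r
library(ddmlong)

# probability that a diffusion with drift 2 and boundary 2 is correct
choice_probability(ddm_parameters(drift = 2, boundary = 2))
#> [1] 0.9820138

# a small synthetic cohort at occasion 1, fitted hierarchically
set.seed(11)
cohort <- cohort_config(subgroup_sizes = c(10, 5, 2, 2, 1),
                        retention = rep(20, 4))
drawn  <- draw_person_trajectories(longitudinal_model(), cohort)
truth  <- subset(drawn$trajectories, time_point == 1)
trials <- generate_trials(truth, cohort)
fit    <- run_mcmc(build_model(trials), n_chains = 2, n_iter = 2000,
                   n_burnin = 1000, seed = 5)
med    <- extract_person_medians(fit)
cor(truth$nu, med$nu)        #> 0.971  (drift recovered across persons)
cor(truth$a, med$a)          #> 0.990
cor(truth$tau_plus, med$tau_plus)  #> 0.987

# closed-form occasion 1-2 correlation of true drift rates implied by
# the default generating model
trajectory_correlation(longitudinal_model()$nu, 1, 2)
#> [1] 0.8042308
```

The recovery correlations say that with 600 trials per person the
hierarchical fit orders people on all three parameters almost exactly as
the generating truth does; the closed-form 0.804 is the ceiling any
rank-order estimate of drift stability between the first two occasions
can reach under the default generating values.

The full pipeline (`run_pipeline(default_config(), outdir)`) runs
simulate → preprocess → fit ×4 occasions → diagnose → analyze → report
and writes every stage's tables (trial CSVs, exclusion log, draws,
diagnostics, person medians, rank-order/growth/q/dropout tables, report
descriptives) into one run directory.

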