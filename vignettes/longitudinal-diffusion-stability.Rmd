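---
title: "Stability and change in diffusion model parameters: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stability and change in diffusion model parameters: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddmlong)
```

`ddmlong` studies whether the core parameters of the Wiener diffusion
model for two-choice response times — drift rate $\nu$, boundary
separation $a$, and non-decision time $\tau$ — behave like traits over a
two-year longitudinal design. It covers the full chain from trial-level
data (or a synthetic stand-in with known ground truth) to four stability
analyses: rank-order stability, mean-level change, individual differences
in change, and within-person profile stability.

## The diffusion model layer

A two-choice decision is modelled as a Wiener process with drift $\nu$
between absorbing boundaries $0$ and $a$, starting at $z = 0.5\,a$. The
diffusion coefficient is fixed at $\sigma = 1$ (all parameter magnitudes
in this package presuppose that convention; drifts near 2, boundaries
near 2, non-decision times near 0.43 s). The upper boundary codes a
correct response, the lower an error, which is why the starting point is
fixed at one half: no response bias is meaningful when the boundaries
code accuracy. Inter-trial variabilities of drift, starting point and
non-decision time are fixed at zero — estimating them tends to harm the
reliability of the main parameters and they carry no substantive meaning
here.

The observed response time decomposes as decision time plus a
non-decision component. Because the emulated task records, on error
trials, only the time of the *corrected* response, errors carry their own
non-decision time: $\tau^-$ applies at the error boundary and absorbs the
response-correction time, $\tau^+$ applies at the correct boundary.
$\tau^- \ge \tau^+$ is typical but not enforced.

The first-passage density is evaluated by switching between the
small-time and large-time series expansions, choosing at each time point
the series needing fewer terms for an absolute truncation error of about
$10^{-7}$; this is stable from 1 ms to 60 s. The trial simulator inverts
the density-implied conditional CDF on a cached 1024-point log-spaced
grid per parameter set; decision times below 0.1 ms are clamped to
0.1 ms. An independent Euler–Maruyama simulation of the raw process
(step $10^{-4}$ s) is kept in the test suite as an oracle for both the
density and the sampler.

Task conditions — five traits crossed with congruent/incongruent block
pairing — enter through effect coding: ten condition effects on drift and
on boundary separation that each sum to zero, so the intercept is the
grand mean across conditions and condition effects never leak into the
person-level quantities carried into stability analyses.

## The synthetic cohort

The generator emulates a five-subgroup cohort (young first-year students,
young second-year students, young non-students, older first-year
students, older non-students) measured at months 0, 6, 12 and 24. The
printed subgroup sizes (113, 109, 26, 63, 58) sum to 369, which the
generator uses as its occasion-1 cohort size; the later-wave retention
counts are 358, 327 and 327, with monotone dropout. Dropout is
completely at random by default; an optional mode makes persons with
higher drift, boundary and non-decision values more likely to miss later
occasions, mirroring the attrition pattern the design anticipates.

Each person's parameter trajectory follows a latent intercept/slope
model per family: the value at occasion $t$ is
$I + S\,\lambda_t + e_t$, with slope loadings fixed at 0 and 1 for the
first two occasions and free at the third and fourth. The default
generating values are the fitted growth solutions of the emulated cohort
(drift: intercept mean 2.104, variance 0.164, slope mean 0.112, variance
0.026, loadings 1.142/1.297; boundary: 2.053/0.274, slope −0.123 with
zero slope variance, loadings 1.233/1.334; non-decision: 0.436/0.006,
slope −0.010 with zero slope variance, loadings −0.358/0.509). Residual
variances printed as 0.000 for the non-decision family are implemented
as $10^{-4}$ so occasion-level change never becomes deterministic.
Draws violating $a > 0.2$ or $\tau^+ > 0.05$ s are redrawn. The error
non-decision time is $\tau^+$ plus a response-correction constant,
0.3 s by default — no empirical value is available for it; it is chosen
so error responses are visibly slower, and it is configurable.

Condition-effect magnitudes (drift $\pm 0.2$, boundary $\mp 0.05$,
congruent blocks favoured) are package defaults: the emulated design
establishes that such effects exist, not their size. Trials are
simulated per 60-trial block, first trial of each block flagged as
warm-up, all flagged as recorded; an artifact injector adds the
contaminant classes the preprocessing rules exist for (fast guesses
below 300 ms, slow outliers above 3 s, non-recorded trials, degraded
low-accuracy participants) with exact bookkeeping of what was injected.

What the generator does *not* emulate: lexical stimulus content,
sequential dependencies, practice effects within a session, slow drifts
of attention, or contaminant RTs inside the admissible window. Passing
tests therefore show that the estimation and analysis chain recovers the
truth under the model's own assumptions — not that real IAT data satisfy
those assumptions.

## Preprocessing

The exclusion steps run in fixed order with a conservation-checked log:
non-recorded trials; the response-time window (trials *below* 300 ms or
*above* 3000 ms dropped — read strictly, so 0.300 s and 3.000 s are
retained); participants whose accuracy falls more than three
interquartile ranges below the first quartile of the per-occasion
accuracy distribution (linear-interpolation quantiles, applied
independently per occasion); and one warm-up trial per block. Accuracy
for the 3-IQR rule is computed on recorded trials before the RT window
by default — task accuracy, not window-conditioned accuracy — with a
switch to compute it after.

## The hierarchical fit

Each occasion is fitted separately (a joint model across occasions is
deliberately out of scope). Per person there are 22 free parameters:
drift intercept plus nine free effect-coded condition deviations (the
tenth is minus their sum), the same for boundary separation, and the two
non-decision times. Person parameters are exchangeable normal draws from
group-level distributions; condition deviations share one spread
hyperparameter per family, with group-level effect means themselves
effect-coded.

Priors are weakly informative package choices recorded verbatim in one
list (`default_priors()`): group drift mean $\mathcal{N}(2, 3^2)$,
positive (zero-truncated) normals centred at 2 and 0.4 s for the
boundary and non-decision group means, half-normal spreads, and
$\mathcal{N}(0, 1)$ / $\mathcal{N}(0, 0.5^2)$ effect means.

Sampling is adaptive Metropolis-within-Gibbs, written for the structure
of this likelihood: the strongly correlated person-level block
$(\nu_p, a_p, \tau^+_p)$ moves under a joint random-walk proposal whose
covariance is learned per person during burn-in (frozen afterwards, so
the retained chain is a fixed Markov kernel); $\tau^-_p$, informed only
by the handful of error trials, gets three cheap sweeps per iteration;
condition deviations move singly; group means are conjugate (truncated)
normal Gibbs draws and group spreads random-walk on the log scale.
Trials with $t - \tau \le 0$ contribute $-\infty$, and initial
non-decision times are set to 0.9 times each person's minimum RT so the
chain starts inside the support. The default geometry is four chains of
6000 iterations with the first 1000 discarded; the same seed reproduces
the draws bit for bit.

Person-level posterior medians of the drift intercept, boundary
intercept and correct non-decision time are the inputs to every
stability analysis. Error non-decision times are estimated (their
medians are kept in fit outputs) but never analysed further — they rest
on too few trials.

## Diagnostics and exclusions

Convergence uses rank-normalized split-$\hat R$ and rank-normalized bulk
effective sample size (autocovariances via FFT, Geyer's initial monotone
positive-pair truncation). A person-occasion parameter vector passes
only if all four of $\nu$, $a$, $\tau^+$, $\tau^-$ have
$\hat R \le 1.01$ and ESS at least 100 effective samples per chain
(400 under the default four chains); failure of any one drops all four,
and the exclusion fraction is logged. Both thresholds are config keys:
the per-chain ESS rule presupposes chains of the default length, so the
smallest bundled smoke runs relax it deliberately and say so.
Zero-variance chains return $\hat R = 1$ and ESS $= 0$ by convention.

Posterior predictive checks draw 500 joint posterior samples, simulate
each person's retained trial design per draw, and compare observed
against predicted-mean RT quartiles (correct and error separately;
linear-interpolation quantiles, matching the preprocessing convention)
and error rates. Persons with ten or fewer observed errors are omitted
from the error-RT panel — their empirical quantiles are too unstable to
be informative.

## Stability analyses

**Rank-order stability** uses Bayesian correlations with a uniform prior
on $(-1, 1)$: the posterior is the sample-correlation likelihood
$p(r \mid \rho) \propto (1-\rho^2)^{(n-1)/2}(1-\rho r)^{(3-2n)/2}$
integrated on a fine grid, and the Bayes factor against $\rho = 0$ is
the Savage–Dickey density ratio at zero. All six occasion pairs are
computed on pairwise-complete cases; cells under 30 cases carry a
small-sample flag, and text output caps Bayes factors at ">999".

**Mean-level change** compares the group-level posterior draws across
occasions through 95% highest density intervals (shortest sorted window,
ties broken leftmost), reporting both intervals, an overlap indicator
and the posterior mean difference per pair.

**Individual differences in change** come from the Bayesian latent
growth curve model described above for the generator, now fitted to the
person-level medians. Estimation is by data augmentation: latent
$(I_i, S_i)$ are drawn per person from their conditional given the
occasions that person was observed at (this is the full-information
missing-data treatment; listwise deletion is a switch), followed by
conjugate draws for the latent means, the latent covariance — in a
regression parameterization, $S = \mu_S + \beta(I - \mu_I) +
\varepsilon$, which avoids the distortions an inverse-Wishart prior
imposes at these sample sizes — the free loadings and the residual
variances. Variance priors are near scale-invariant inverse gammas;
three chains of 10 000 draws with 5 000 burn-in are the default.

The model is fitted twice. The first pass leaves the intercept–slope
covariance and the slope variance free; the covariance is then fixed to
zero when its 95% credible interval includes zero, and the slope
variance when its posterior median falls below 5% of the intercept
variance's median — the operational reading of "estimated to be zero"
for a parameter that is positive by construction, with 5% chosen as a
negligible share of the stable between-person spread. The refit with the
triggered zeros is reported, with fixing flags.

Fit is summarized by Bayesian analogues of GammaHat and CFI: per
retained draw the deviance against the saturated model (saturated
log-likelihood by closed form, or EM over missingness patterns) is
corrected by the effective number of parameters $p_D$ (mean deviance
minus deviance at the posterior mean), giving a draw-level
$\chi^2$ that centres at its degrees of freedom under a true model;
$\mathrm{GammaHat} = p/(p + 2(\chi^2 - df)/N)$ with $p = 4$, and CFI
uses the independence model as baseline. Posterior means are reported;
well-specified simulations sit above 0.99 on both.

**Profile stability** z-standardizes the three parameters separately —
per occasion by default, so profiles encode relative standing with
mean-level change removed; pooled standardization is available as an
option — and computes, per person and occasion pair, the Pearson
correlation across the three paired z-scores (the q correlation).
Zero-variance profiles yield missing q and are counted. Only
descriptives (mean, SD, median, N) are reported, plus density plots.

**Dropout analysis**: persons missing at any later occasion (by design
or by convergence exclusion) are compared with complete persons on each
occasion-1 parameter through a default-prior two-sample Bayes-factor
t-test (zero-centred Cauchy with scale $\sqrt{2}/2$ on the standardized
effect, evaluated via the usual inverse-gamma mixture integral).

## Problem sizes used by the bundled checks

The test suite and the acceptance script scale the study design down to
sizes the package chooses for its demonstrations: parameter recovery
uses 20 participants with 600 trials each and two chains of 2000
iterations (recovery correlations are typically 0.97–0.99); the
end-to-end qualitative run keeps the full cohort (369 persons with the
study's retention) but 20 trials per block and two chains of 1300
iterations, gating ESS at 100 per chain; growth-curve recovery uses 300
persons at the default chain geometry; the acceptance script's pipeline
halves the cohort. Exclusion fractions under shortened chains run above
the full-geometry regime — the per-chain ESS rule presupposes the
default chain length — which the affected runs state explicitly.

## Known limitations

The sampler estimates one occasion at a time; posterior medians carried
into stage two discard within-person posterior uncertainty, so stability
coefficients inherit a (hierarchically shrunken) attenuation that the
closed-form trajectory correlation quantifies for the generator. The
growth model's free loadings are weakly identified when both the slope
mean and slope variance are near zero — their posteriors then simply
return the prior scale, as the non-decision family illustrates. Profile
q correlations over three values are coarse by construction and are
reported descriptively only.
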