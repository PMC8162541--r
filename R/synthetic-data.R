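# Synthetic longitudinal IAT-like cohorts with known ground truth.
# Person-level parameter trajectories follow a latent intercept/slope
# growth structure; trials are then simulated from the diffusion model
# with effect-coded condition effects and dual non-decision times.

#' Growth parameters for one diffusion parameter family
#'
#' Latent intercept/slope model for the trajectory of one person-level
#' parameter across the four occasions: value at occasion t is
#' \eqn{I + S \lambda_t + e_t} with \eqn{(I, S)} bivariate normal and
#' occasion residuals \eqn{e_t \sim N(0, \epsilon_t)}. Loadings are fixed
#' to 0 at occasion 1 and 1 at occasion 2; occasions 3 and 4 carry free
#' loadings.
#'
#' @param mean_i,var_i Latent intercept mean and variance.
#' @param mean_s,var_s Latent slope mean and variance.
#' @param cov_is Intercept-slope covariance.
#' @param loadings Slope loadings, length 4; first two must be 0 and 1.
#' @param resid Residual variances per occasion, length 4, >= 0.
#' @return An object of class \code{growth_params}.
#' @export
growth_params <- function(mean_i, var_i, mean_s, var_s, cov_is = 0,
                          loadings = c(0, 1, 1, 1),
                          resid = rep(0, 4)) {
  stopifnot(length(loadings) == 4, length(resid) == 4)
  if (loadings[1] != 0 || loadings[2] != 1) {
    stop("growth_params: slope loadings must be fixed to 0 (occasion 1) and 1 (occasion 2)",
         call. = FALSE)
  }
  if (var_i < 0 || var_s < 0 || any(resid < 0)) {
    stop("growth_params: variances must be >= 0", call. = FALSE)
  }
  if (var_i * var_s > 0 && abs(cov_is) > sqrt(var_i * var_s)) {
    stop("growth_params: covariance implies |correlation| > 1", call. = FALSE)
  }
  structure(list(mean_i = mean_i, var_i = var_i, mean_s = mean_s,
                 var_s = var_s, cov_is = cov_is, loadings = loadings,
                 resid = resid),
            class = "growth_params")
}

#' Default longitudinal generating model
#'
#' The default generating values for the three parameter families are the
#' fitted growth-curve solutions of the two-year IAT cohort this package's
#' synthetic design emulates: drift rate grows (positive slope mean with
#' real slope variance), boundary separation declines with zero slope
#' variance, and the correct non-decision time is essentially flat with
#' zero slope variance. Residual variances reported as 0.000 for the
#' non-decision family are implemented as 1e-4 so occasion-level change is
#' not perfectly deterministic. The error non-decision time is the
#' correct one plus a response-correction constant (default 0.3 s).
#'
#' @param nu,a,tau \code{\link{growth_params}} for drift rate, boundary
#'   separation, and the correct non-decision time.
#' @param correction Additive response-correction constant (s):
#'   \code{tau_minus = tau_plus + correction}.
#' @return An object of class \code{longitudinal_model}.
#' @export
longitudinal_model <- function(
    nu = growth_params(2.104, 0.164, 0.112, 0.026, 0,
                       c(0, 1, 1.142, 1.297),
                       c(0.020, 0.036, 0.060, 0.082)),
    a = growth_params(2.053, 0.274, -0.123, 0, 0,
                      c(0, 1, 1.233, 1.334),
                      c(0.060, 0.020, 0.036, 0.045)),
    tau = growth_params(0.436, 0.006, -0.010, 0, 0,
                        c(0, 1, -0.358, 0.509),
                        c(0.001, 1e-4, 0.001, 0.002)),
    correction = 0.3) {
  stopifnot(inherits(nu, "growth_params"), inherits(a, "growth_params"),
            inherits(tau, "growth_params"), correction >= 0)
  structure(list(nu = nu, a = a, tau = tau, correction = correction),
            class = "longitudinal_model")
}

#' Default condition-effect magnitudes for the synthetic design
#'
#' Congruent blocks get a drift advantage of +0.2 and a boundary effect of
#' -0.05; incongruent blocks the opposite. These magnitudes are package
#' defaults (the emulated design only establishes that such effects
#' exist); they are configurable through \code{\link{cohort_config}}.
#' @return A \code{\link{condition_effects}} object.
#' @export
default_cohort_effects <- function() {
  labs <- default_condition_labels()
  congruent <- grepl(":congruent$", labs)
  condition_effects(labs,
                    drift_effects = ifelse(congruent, 0.2, -0.2),
                    boundary_effects = ifelse(congruent, -0.05, 0.05))
}

#' Cohort design configuration
#'
#' The emulated study design: five subgroups (young first-year students,
#' young second-year students, young non-students, older first-year
#' students, older non-students), four occasions at months 0/6/12/24 with
#' non-increasing retention, age distributions per age group, and the
#' trial design of five traits x two congruency blocks x 60 test trials.
#'
#' @param subgroup_sizes Sizes of the five subgroups at occasion 1.
#' @param retention Participants present per occasion (non-increasing;
#'   first entry must equal the total of \code{subgroup_sizes}).
#' @param age_young,age_old Mean and SD of age for the young (subgroups
#'   1-3) and older (subgroups 4-5) participants.
#' @param trials_per_block Test trials per trait x congruency block.
#' @param training_trials Training-block trial count (design bookkeeping
#'   only; training responses are not modelled).
#' @param effects A \code{\link{condition_effects}} object.
#' @param months Occasion labels in months.
#' @param dropout One of \code{"random"} (completely at random) or
#'   \code{"parameter"} (persons with higher drift, boundary and
#'   non-decision values are more likely to miss later occasions).
#' @return An object of class \code{cohort_config}.
#' @export
cohort_config <- function(subgroup_sizes = c(113, 109, 26, 63, 58),
                          retention = c(369, 358, 327, 327),
                          age_young = c(mean = 21.57, sd = 2.20),
                          age_old = c(mean = 67.76, sd = 5.31),
                          trials_per_block = 60L,
                          training_trials = 20L,
                          effects = default_cohort_effects(),
                          months = c(0, 6, 12, 24),
                          dropout = c("random", "parameter")) {
  dropout <- match.arg(dropout)
  if (sum(subgroup_sizes) != retention[1]) {
    stop("cohort_config: subgroup sizes must sum to the occasion-1 N",
         call. = FALSE)
  }
  if (any(diff(retention) > 0)) {
    stop("cohort_config: retention must be non-increasing", call. = FALSE)
  }
  structure(list(subgroup_sizes = subgroup_sizes, retention = retention,
                 age_young = age_young, age_old = age_old,
                 trials_per_block = as.integer(trials_per_block),
                 training_trials = as.integer(training_trials),
                 effects = effects, months = months, dropout = dropout),
            class = "cohort_config")
}

draw_growth_values <- function(gp, n) {
  # (I, S) bivariate normal via the lower Cholesky factor, then occasion
  # values I + S * lambda_t + e_t
  l11 <- sqrt(gp$var_i)
  l21 <- if (gp$var_i > 0) gp$cov_is / l11 else 0
  l22 <- sqrt(max(gp$var_s - l21^2, 0))
  z <- matrix(rnorm(2 * n), n, 2)
  I <- gp$mean_i + l11 * z[, 1]
  S <- gp$mean_s + l21 * z[, 1] + l22 * z[, 2]
  vals <- outer(I, rep(1, 4)) + outer(S, gp$loadings)
  vals <- vals + matrix(rnorm(4 * n, 0, rep(sqrt(gp$resid), each = n)), n, 4)
  list(I = I, S = S, values = vals)
}

#' Draw person-level parameter trajectories
#'
#' Draws each person's latent intercept and slope per parameter family,
#' forms their occasion values, and applies the design's truncation rules:
#' trajectories with any boundary separation at or below 0.2 or any
#' correct non-decision time at or below 0.05 s are redrawn (configuration
#' error after 1000 attempts). Also assigns subgroups, ages and the
#' dropout mask implied by the retention counts. Reproducible under
#' \code{set.seed()}.
#'
#' @param model A \code{\link{longitudinal_model}}.
#' @param cohort A \code{\link{cohort_config}}.
#' @return List with \code{trajectories} (long data.frame: participant,
#'   subgroup, age group, occasion, observed flag, nu, a, tau_plus,
#'   tau_minus) and \code{latents} (participant x family ground-truth I
#'   and S).
#' @export
draw_person_trajectories <- function(model, cohort) {
  n <- sum(cohort$subgroup_sizes)
  fams <- c("nu", "a", "tau")
  vals <- list()
  lat <- list()
  for (f in fams) {
    g <- draw_growth_values(model[[f]], n)
    # redraw rows violating the truncation region
    bad <- if (f == "a") {
      which(apply(g$values, 1, function(x) any(x <= 0.2)))
    } else if (f == "tau") {
      which(apply(g$values, 1, function(x) any(x <= 0.05)))
    } else integer(0)
    tries <- 0
    while (length(bad)) {
      tries <- tries + 1
      if (tries > 1000) {
        stop("draw_person_trajectories: truncation region too restrictive (",
             f, ")", call. = FALSE)
      }
      g2 <- draw_growth_values(model[[f]], length(bad))
      g$I[bad] <- g2$I; g$S[bad] <- g2$S
      g$values[bad, ] <- g2$values
      bad <- bad[if (f == "a") apply(g$values[bad, , drop = FALSE], 1,
                                     function(x) any(x <= 0.2))
                 else apply(g$values[bad, , drop = FALSE], 1,
                            function(x) any(x <= 0.05))]
    }
    vals[[f]] <- g$values
    lat[[f]] <- data.frame(participant_id = sprintf("P%03d", seq_len(n)),
                           family = f, intercept = g$I, slope = g$S)
  }
  ids <- sprintf("P%03d", seq_len(n))
  subgroup <- rep(seq_along(cohort$subgroup_sizes), cohort$subgroup_sizes)
  age_group <- ifelse(subgroup <= 3, "young", "old")
  age <- ifelse(age_group == "young",
                rnorm(n, cohort$age_young[["mean"]], cohort$age_young[["sd"]]),
                rnorm(n, cohort$age_old[["mean"]], cohort$age_old[["sd"]]))

  # monotone dropout to the configured retention counts
  observed <- matrix(TRUE, n, 4)
  present <- seq_len(n)
  for (t in 2:4) {
    keep_n <- cohort$retention[t]
    if (keep_n < length(present)) {
      if (cohort$dropout == "random") {
        keep <- sort(sample(present, keep_n))
      } else {
        z <- scale(vals$nu[present, 1])[, 1] + scale(vals$a[present, 1])[, 1] +
          scale(vals$tau[present, 1])[, 1]
        w <- exp(-0.5 * z)   # higher parameter levels -> more likely to drop
        keep <- sort(sample(present, keep_n, prob = w / sum(w)))
      }
      observed[setdiff(present, keep), t:4] <- FALSE
      present <- keep
    }
  }

  traj <- data.frame(
    participant_id = rep(ids, each = 4),
    subgroup = rep(subgroup, each = 4),
    age_group = rep(age_group, each = 4),
    age = rep(round(age, 1), each = 4),
    time_point = rep(1:4, n),
    month = rep(cohort$months, n),
    observed = as.vector(t(observed)),
    nu = as.vector(t(vals$nu)),
    a = as.vector(t(vals$a)),
    tau_plus = as.vector(t(vals$tau)),
    stringsAsFactors = FALSE)
  traj$tau_minus <- traj$tau_plus + model$correction
  list(trajectories = traj, latents = do.call(rbind, lat))
}

#' Generate trial-level data for a cohort
#'
#' Simulates, for every observed participant x occasion, one 60-trial test
#' block per trait x congruency condition (600 test trials in total) from
#' the diffusion model with the cohort's condition effects applied to that
#' person's occasion parameters. The first trial of each block is flagged
#' as a warm-up trial; all trials are flagged as recorded. Error-response
#' RTs include the response-correction constant through the error
#' non-decision time.
#'
#' @param trajectories The \code{trajectories} element of
#'   \code{\link{draw_person_trajectories}}.
#' @param cohort A \code{\link{cohort_config}}.
#' @return Trial data.frame with columns \code{participant_id},
#'   \code{subgroup}, \code{age_group}, \code{time_point}, \code{trait},
#'   \code{congruency}, \code{block_index}, \code{trial_index},
#'   \code{warmup_flag}, \code{recorded_flag}, \code{correct},
#'   \code{rt_s}.
#' @export
generate_trials <- function(trajectories, cohort = cohort_config()) {
  eff <- cohort$effects
  nb <- cohort$trials_per_block
  rows <- trajectories[trajectories$observed, , drop = FALSE]
  out <- vector("list", nrow(rows) * 10L)
  k <- 0L
  for (r in seq_len(nrow(rows))) {
    base <- ddm_parameters(rows$nu[r], rows$a[r], 0.5,
                           rows$tau_plus[r], rows$tau_minus[r])
    for (b in seq_along(eff$labels)) {
      cond <- eff$labels[b]
      p <- apply_condition_effects(base, eff, cond)
      tr <- simulate_trials(p, nb)
      tc <- strsplit(cond, ":", fixed = TRUE)[[1]]
      k <- k + 1L
      out[[k]] <- data.frame(
        participant_id = rows$participant_id[r],
        subgroup = rows$subgroup[r],
        age_group = rows$age_group[r],
        time_point = rows$time_point[r],
        trait = tc[1], congruency = tc[2],
        block_index = b,
        trial_index = seq_len(nb),
        warmup_flag = seq_len(nb) == 1L,
        recorded_flag = TRUE,
        correct = tr$correct,
        rt_s = round(tr$rt, 6),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out[seq_len(k)])
}

#' Inject contaminant artifacts into a trial table
#'
#' Adds the artifact classes the preprocessing filters exist for:
#' fast guesses (RT drawn below 0.3 s), slow outliers (RT above 3 s),
#' non-recorded trials (recorded flag cleared), and designated
#' low-accuracy participants whose responses are re-drawn as coin flips
#' with the given accuracy. Rates apply per eligible trial; exact counts
#' of every injected artifact are returned.
#'
#' @param trials A trial table from \code{\link{generate_trials}}.
#' @param fast_rate,slow_rate,nonrecorded_rate Rates in [0, 0.5].
#' @param low_accuracy_ids Participant ids to degrade.
#' @param low_accuracy Accuracy for degraded participants.
#' @return List: \code{trials} (modified table) and \code{counts} (named
#'   counts of injected artifacts).
#' @export
inject_artifacts <- function(trials, fast_rate = 0, slow_rate = 0,
                             nonrecorded_rate = 0,
                             low_accuracy_ids = character(0),
                             low_accuracy = 0.5) {
  rates <- c(fast_rate, slow_rate, nonrecorded_rate)
  if (any(rates < 0) || any(rates > 0.5)) {
    stop("inject_artifacts: rates must lie in [0, 0.5]", call. = FALSE)
  }
  n <- nrow(trials)
  free <- seq_len(n)
  pick <- function(rate) {
    k <- round(rate * n)
    if (k == 0) return(integer(0))
    sel <- sample(free, min(k, length(free)))
    free <<- setdiff(free, sel)
    sel
  }
  i_fast <- pick(fast_rate)
  i_slow <- pick(slow_rate)
  i_nr <- pick(nonrecorded_rate)
  trials$rt_s[i_fast] <- round(runif(length(i_fast), 0.10, 0.29), 6)
  trials$rt_s[i_slow] <- round(runif(length(i_slow), 3.05, 6.00), 6)
  trials$recorded_flag[i_nr] <- FALSE
  n_low <- 0L
  if (length(low_accuracy_ids)) {
    sel <- trials$participant_id %in% low_accuracy_ids
    trials$correct[sel] <- rbinom(sum(sel), 1, low_accuracy)
    n_low <- sum(sel)
  }
  list(trials = trials,
       counts = c(fast = length(i_fast), slow = length(i_slow),
                  nonrecorded = length(i_nr), low_accuracy_trials = n_low))
}

#' Closed-form correlation of true parameter values between two occasions
#'
#' Variance-component formula under the latent intercept/slope model:
#' \deqn{cor(y_{t_1}, y_{t_2}) = \frac{\sigma^2_I + (\lambda_{t_1} +
#'   \lambda_{t_2})\sigma_{IS} + \lambda_{t_1}\lambda_{t_2}\sigma^2_S}
#'   {\sqrt{V_{t_1} V_{t_2}}}}
#' with \eqn{V_t = \sigma^2_I + 2\lambda_t\sigma_{IS} +
#' \lambda_t^2\sigma^2_S + \epsilon_t}.
#'
#' @param gp A \code{\link{growth_params}} object.
#' @param t1,t2 Occasion indices (1-4).
#' @return The implied correlation.
#' @export
trajectory_correlation <- function(gp, t1, t2) {
  l1 <- gp$loadings[t1]; l2 <- gp$loadings[t2]
  num <- gp$var_i + (l1 + l2) * gp$cov_is + l1 * l2 * gp$var_s
  v <- function(l, e) gp$var_i + 2 * l * gp$cov_is + l^2 * gp$var_s + e
  num / sqrt(v(l1, gp$resid[t1]) * v(l2, gp$resid[t2]))
}

#' Write / read the trial CSV dialect
#'
#' Trial tables are exchanged as plain CSV with a fixed column set and
#' RTs in seconds with six decimals.
#' @param trials Trial data.frame.
#' @param path File path.
#' @return \code{read_trials} returns the trial data.frame.
#' @export
write_trials <- function(trials, path) {
  cols <- c("participant_id", "subgroup", "age_group", "time_point",
            "trait", "congruency", "block_index", "trial_index",
            "warmup_flag", "recorded_flag", "correct", "rt_s")
  miss <- setdiff(cols, names(trials))
  if (length(miss)) {
    stop("write_trials: missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out <- trials[, cols]
  out$rt_s <- sprintf("%.6f", out$rt_s)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  tr <- read.csv(path, stringsAsFactors = FALSE)
  tr$warmup_flag <- as.logical(tr$warmup_flag)
  tr$recorded_flag <- as.logical(tr$recorded_flag)
  tr$rt_s <- as.numeric(tr$rt_s)
  tr
}
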