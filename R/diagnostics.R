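# Convergence diagnostics (rank-normalized split R-hat and bulk ESS),
# the joint person-level exclusion rule, and posterior predictive checks.

as_chain_matrix <- function(draws) {
  if (is.null(dim(draws))) draws <- matrix(draws, ncol = 1)
  draws
}

# split each chain in half (dropping the middle draw of odd chains)
split_chains <- function(mat) {
  n <- nrow(mat)
  h <- n %/% 2
  cbind(mat[seq_len(h), , drop = FALSE],
        mat[(n - h + 1):n, , drop = FALSE])
}

# Blom-offset rank normalization over the pooled draws
rank_normalize <- function(mat) {
  S <- length(mat)
  z <- qnorm((rank(mat, ties.method = "average") - 3 / 8) / (S + 1 / 4))
  matrix(z, nrow(mat), ncol(mat))
}

#' Rank-normalized split R-hat
#'
#' Potential-scale-reduction statistic computed on rank-normalized,
#' split chains. Chains with zero variance (all draws equal) return
#' exactly 1 by convention.
#'
#' @param draws Iteration x chain matrix (at least 2 chains, at least 4
#'   retained iterations each).
#' @return Scalar R-hat.
#' @export
rhat <- function(draws) {
  mat <- as_chain_matrix(draws)
  if (ncol(mat) < 2) {
    stop("rhat: at least 2 chains required; split a single chain in half ",
         "and pass the halves as chains", call. = FALSE)
  }
  if (nrow(mat) < 4) stop("rhat: need >= 4 iterations per chain", call. = FALSE)
  if (all(mat == mat[1])) return(1)
  z <- rank_normalize(split_chains(mat))
  n <- nrow(z); m <- ncol(z)
  means <- colMeans(z)
  vars <- apply(z, 2, var)
  B <- n * var(means)
  W <- mean(vars)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Rank-normalized bulk effective sample size
#'
#' Effective number of independent draws for bulk quantities, computed on
#' rank-normalized split chains by autocorrelation summation with Geyer's
#' initial monotone positive-pair truncation. A constant chain returns 0.
#'
#' @param draws Iteration x chain matrix, or a single vector (split in
#'   half automatically).
#' @return Scalar ESS.
#' @export
bulk_ess <- function(draws) {
  mat <- as_chain_matrix(draws)
  if (nrow(mat) < 4) stop("bulk_ess: need >= 4 iterations", call. = FALSE)
  if (all(mat == mat[1])) return(0)
  z <- rank_normalize(split_chains(mat))
  n <- nrow(z); m <- ncol(z)
  vars <- apply(z, 2, var)
  W <- mean(vars)
  var_plus <- (n - 1) / n * W + n * var(colMeans(z)) / n
  # per-chain autocovariances (biased estimator), via zero-padded FFT
  acov_one <- function(x) {
    x <- x - mean(x)
    m2 <- stats::nextn(2 * n, 2)
    f <- stats::fft(c(x, rep(0, m2 - n)))
    Re(stats::fft(Mod(f)^2, inverse = TRUE))[seq_len(n)] / m2 / n
  }
  acov <- vapply(seq_len(m), function(j) acov_one(z[, j]), numeric(n))
  mean_acov <- rowMeans(acov)
  rho <- 1 - (W - mean_acov) / var_plus
  # Geyer initial positive + monotone sequence on adjacent-pair sums
  tau <- rho[1]
  prev_pair <- Inf
  t <- 2
  while (t + 1 <= length(rho)) {
    pair <- rho[t] + rho[t + 1]
    if (pair < 0) break
    pair <- min(pair, prev_pair)
    tau <- tau + 2 * pair
    prev_pair <- pair
    t <- t + 2
  }
  max(n * m / max(tau, 1e-12), 0)
}

#' Diagnostics table for the person-level parameters of a fit
#'
#' Computes R-hat and bulk ESS per person for the four person-level
#' parameters (drift intercept, boundary intercept, both non-decision
#' times) and flags each against the acceptance thresholds.
#'
#' @param fit A \code{\link{run_mcmc}} result.
#' @param rhat_threshold,ess_threshold Pass thresholds (defaults 1.01
#'   and 400).
#' @return data.frame: participant_id, parameter, rhat, ess, pass.
#' @export
fit_diagnostics <- function(fit, rhat_threshold = 1.01, ess_threshold = 400) {
  pars <- c("nu", "a", "tau_plus", "tau_minus")
  rows <- list()
  k <- 0L
  for (id in fit$person_ids) {
    for (par in pars) {
      d <- draws_of(fit, paste0(par, "[", id, "]"))
      r <- rhat(d)
      e <- bulk_ess(d)
      k <- k + 1L
      rows[[k]] <- data.frame(participant_id = id, parameter = par,
                              rhat = r, ess = e,
                              pass = (r <= rhat_threshold) & (e >= ess_threshold),
                              stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Joint exclusion rule on person-level diagnostics
#'
#' A person's full parameter set (drift, boundary and both non-decision
#' times) is excluded at a time point when ANY of the four parameters
#' shows signs of non-convergence (fails R-hat or ESS). The rule is
#' monotone: additional failures can only add exclusions.
#'
#' @param medians A person-median table from
#'   \code{\link{extract_person_medians}}.
#' @param diagnostics A table from \code{\link{fit_diagnostics}}.
#' @return List: \code{medians} (with all four parameter columns set to
#'   \code{NA} for excluded persons), \code{excluded} (ids),
#'   \code{fraction} (excluded person-parameter vectors / persons with
#'   diagnostics), and \code{log}.
#' @export
apply_exclusion_rules <- function(medians, diagnostics) {
  bad <- unique(diagnostics$participant_id[!diagnostics$pass])
  out <- medians
  sel <- out$participant_id %in% bad
  out[sel, c("nu", "a", "tau_plus", "tau_minus")] <- NA_real_
  n_diag <- length(unique(diagnostics$participant_id))
  frac <- if (n_diag > 0) length(bad) / n_diag else 0
  list(medians = out, excluded = bad, fraction = frac,
       log = data.frame(step = "convergence",
                        reason = "nonconverged_person_vector",
                        n_excluded = length(bad), fraction = frac))
}

#' Posterior predictive check of RT quartiles and error rates
#'
#' Randomly selects \code{n_draws} joint posterior draws; for each draw
#' simulates every person's observed trial design (their retained trial
#' counts per condition) from the diffusion model with that draw's
#' person-level parameters and condition effects, then summarizes each
#' simulated data set by per-person RT quartiles (correct and error
#' responses separately, linear-interpolation quantiles) and error rates.
#' The predicted value of each statistic is the mean over draws. Persons
#' with 10 or fewer observed errors are omitted from the error-RT output
#' (but kept in the accuracy output).
#'
#' @param fit A \code{\link{run_mcmc}} result.
#' @param trials The preprocessed trial table the model was fitted to.
#' @param n_draws Number of posterior draws (default 500).
#' @return data.frame: participant_id, statistic, observed, predicted.
#' @export
posterior_predictive_check <- function(fit, trials, n_draws = 500) {
  total <- dim(fit$draws)[1] * fit$n_chains
  if (n_draws > total) {
    stop("posterior_predictive_check: n_draws (", n_draws,
         ") exceeds retained draws (", total, ")", call. = FALSE)
  }
  tr <- normalize_fit_trials(trials, fit$conditions)
  tr <- tr[tr$participant_id %in% fit$person_ids, , drop = FALSE]
  sel <- sample.int(total, n_draws)
  it <- (sel - 1) %% dim(fit$draws)[1] + 1
  ch <- (sel - 1) %/% dim(fit$draws)[1] + 1
  qs <- c(0.25, 0.5, 0.75)
  rows <- list(); k <- 0L
  for (id in fit$person_ids) {
    sub <- tr[tr$participant_id == id, , drop = FALSE]
    cond_counts <- table(factor(sub$condition, levels = fit$conditions))
    obs_cor <- sub$rt[sub$correct == 1]
    obs_err <- sub$rt[sub$correct == 0]
    n_err <- length(obs_err)
    pred <- matrix(NA_real_, n_draws, 7)  # q1-3 correct, q1-3 error, errrate
    for (d in seq_len(n_draws)) {
      g <- function(par) fit$draws[it[d], ch[d], par]
      nu_eff <- c(vapply(1:9, function(c) g(paste0("nu_eff[", id, ",", c, "]")),
                         numeric(1)))
      a_eff <- c(vapply(1:9, function(c) g(paste0("a_eff[", id, ",", c, "]")),
                        numeric(1)))
      nu_eff <- c(nu_eff, -sum(nu_eff))
      a_eff <- c(a_eff, -sum(a_eff))
      sim_rt <- numeric(0); sim_cor <- integer(0)
      for (ci in seq_along(fit$conditions)) {
        nb <- cond_counts[[ci]]
        if (nb == 0) next
        p <- ddm_parameters(g(paste0("nu[", id, "]")) + nu_eff[ci],
                            g(paste0("a[", id, "]")) + a_eff[ci], 0.5,
                            g(paste0("tau_plus[", id, "]")),
                            g(paste0("tau_minus[", id, "]")))
        s <- simulate_trials(p, nb, n_grid = 384L)
        sim_rt <- c(sim_rt, s$rt); sim_cor <- c(sim_cor, s$correct)
      }
      sc <- sim_rt[sim_cor == 1]; se <- sim_rt[sim_cor == 0]
      if (length(sc) >= 3) pred[d, 1:3] <- quantile(sc, qs, type = 7)
      if (length(se) >= 3) pred[d, 4:6] <- quantile(se, qs, type = 7)
      pred[d, 7] <- mean(sim_cor == 0)
    }
    pm <- colMeans(pred, na.rm = TRUE)
    stat_rows <- data.frame(
      participant_id = id,
      statistic = c("rt_correct_q25", "rt_correct_q50", "rt_correct_q75",
                    "rt_error_q25", "rt_error_q50", "rt_error_q75",
                    "error_rate"),
      observed = c(if (length(obs_cor) >= 3) quantile(obs_cor, qs, type = 7)
                   else rep(NA_real_, 3),
                   if (n_err >= 3) quantile(obs_err, qs, type = 7)
                   else rep(NA_real_, 3),
                   n_err / nrow(sub)),
      predicted = pm, stringsAsFactors = FALSE)
    if (n_err <= 10) {
      stat_rows <- stat_rows[!grepl("^rt_error", stat_rows$statistic), ]
    }
    k <- k + 1L
    rows[[k]] <- stat_rows
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
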