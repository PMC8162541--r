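# Per-occasion hierarchical Bayesian estimation of the diffusion model:
# person-level drift and boundary intercepts with effect-coded condition
# deviations, dual non-decision times (correct / corrected-error), starting
# point fixed at 0.5, inter-trial variabilities fixed at zero.

#' Model specification for the per-occasion hierarchical fit
#'
#' Fixes the structural choices of the estimation model: relative starting
#' point 0.5, zero inter-trial variabilities, ten effect-coded conditions
#' (nine free deviations per parameter family, the tenth is minus their
#' sum), and separate non-decision times for correct and error responses.
#' Each person therefore carries 22 free parameters: 1 + 9 for drift,
#' 1 + 9 for boundary separation, and the two non-decision times.
#'
#' @param conditions Character vector of exactly 10 condition labels.
#' @param min_trials Minimum retained trials for a participant to enter
#'   the fit (default 20); participants below it are dropped with a
#'   warning.
#' @return An object of class \code{ddm_model_spec}.
#' @export
ddm_model_spec <- function(conditions = default_condition_labels(),
                           min_trials = 20L) {
  if (length(conditions) != 10L) {
    stop("ddm_model_spec: exactly 10 condition labels required", call. = FALSE)
  }
  structure(list(z_rel = 0.5, variabilities = 0, conditions = conditions,
                 min_trials = as.integer(min_trials),
                 n_person_params = 22L),
            class = "ddm_model_spec")
}

#' Default prior configuration
#'
#' Weakly informative hyperpriors for the group-level parameters. These
#' values are this package's own choices (chosen, not taken from any
#' reference fit): group drift mean ~ Normal(2, 3^2); group boundary and
#' non-decision means ~ positive (zero-truncated) normals centred near
#' the typical magnitudes 2 and 0.4 s; group spreads half-normal; effect
#' means normal around zero with a shared half-normal spread per family.
#' Every hyperparameter lives in this one list so a fit's prior setup can
#' be recorded verbatim.
#'
#' @return Named list of prior hyperparameters.
#' @export
default_priors <- function() {
  list(mu_nu_mean = 2, mu_nu_sd = 3,
       mu_a_mean = 2, mu_a_sd = 3,          # truncated > 0
       mu_tau_mean = 0.4, mu_tau_sd = 0.5,  # truncated > 0
       sigma_nu_scale = 1, sigma_a_scale = 1, sigma_tau_scale = 0.3,
       delta_nu_sd = 1, delta_a_sd = 0.5,
       sigma_nu_eff_scale = 0.5, sigma_a_eff_scale = 0.5,
       note = "package-chosen weakly informative defaults")
}

# normalize a trial table to the columns the fit needs
normalize_fit_trials <- function(trials, conditions) {
  rt_col <- if ("rt_s" %in% names(trials)) "rt_s" else "rt"
  if (!rt_col %in% names(trials)) {
    stop("build_model: trials need an 'rt_s' (or 'rt') column", call. = FALSE)
  }
  if (!"condition" %in% names(trials)) {
    if (all(c("trait", "congruency") %in% names(trials))) {
      trials$condition <- paste(trials$trait, trials$congruency, sep = ":")
    } else {
      stop("build_model: trials need 'condition' or 'trait'+'congruency'",
           call. = FALSE)
    }
  }
  unknown <- setdiff(unique(trials$condition), conditions)
  if (length(unknown)) {
    stop("build_model: unknown condition label(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  data.frame(participant_id = trials$participant_id,
             condition = trials$condition,
             correct = as.integer(trials$correct),
             rt = trials[[rt_col]])
}

#' Build the hierarchical diffusion model for one time point
#'
#' Assembles the data structures and log-density for the per-occasion
#' hierarchical model. The trial log-likelihood uses the first-passage
#' density with the correct-response non-decision time on correct-boundary
#' terms and the error non-decision time on error-boundary terms;
#' condition effects enter additively on drift and boundary separation.
#' Participants with fewer than \code{spec$min_trials} retained trials are
#' excluded from the fit with a warning. All-correct participants are
#' allowed: their error non-decision time is informed only by the
#' hierarchy.
#'
#' @param trials Preprocessed trial table for one time point with columns
#'   \code{participant_id}, \code{correct}, \code{rt_s} (or \code{rt}),
#'   and either \code{condition} or \code{trait} + \code{congruency}.
#' @param spec A \code{\link{ddm_model_spec}}.
#' @param priors A prior list as from \code{\link{default_priors}}.
#' @return An object of class \code{ddm_model} carrying the indexed data,
#'   the spec and priors, and usable with \code{\link{run_mcmc}} and
#'   \code{\link{model_log_density}}.
#' @export
build_model <- function(trials, spec = ddm_model_spec(),
                        priors = default_priors()) {
  tr <- normalize_fit_trials(trials, spec$conditions)
  cnt <- table(tr$participant_id)
  dropped <- names(cnt)[cnt < spec$min_trials]
  if (length(dropped)) {
    warning("build_model: excluding ", length(dropped),
            " participant(s) with fewer than ", spec$min_trials,
            " trials: ", paste(dropped, collapse = ", "), call. = FALSE)
    tr <- tr[!tr$participant_id %in% dropped, , drop = FALSE]
  }
  persons <- sort(unique(tr$participant_id))
  if (length(persons) < 2L) {
    stop("build_model: at least 2 participants required", call. = FALSE)
  }
  if (any(tapply(tr$correct, tr$participant_id, sum) < 1)) {
    stop("build_model: every participant needs at least one correct trial",
         call. = FALSE)
  }
  structure(
    list(person_ids = persons,
         excluded_ids = dropped,
         person_index = match(tr$participant_id, persons) - 1L,
         cond_index = match(tr$condition, spec$conditions) - 1L,
         correct = tr$correct,
         rt = tr$rt,
         spec = spec,
         priors = priors),
    class = "ddm_model")
}

#' @export
print.ddm_model <- function(x, ...) {
  cat(sprintf(
    "Hierarchical diffusion model: %d participants, %d trials, %d conditions\n",
    length(x$person_ids), length(x$rt), length(x$spec$conditions)))
  cat(sprintf("  free person-level parameters: %d x %d = %d (+ hyperparameters)\n",
              x$spec$n_person_params, length(x$person_ids),
              x$spec$n_person_params * length(x$person_ids)))
  invisible(x)
}

#' Joint log density of the hierarchical model at a parameter point
#'
#' Evaluates the unnormalized posterior log density: the sum over trials
#' of the log first-passage density plus the person-level and group-level
#' log priors (half-normal for spreads; positivity constraints enter as
#' domain indicators). Intended for testing and for small-scale
#' exploration; the sampler evaluates the same quantity incrementally.
#'
#' @param model A \code{\link{build_model}} object.
#' @param state Named list with vectors \code{nu}, \code{a},
#'   \code{tau_plus}, \code{tau_minus} (one entry per participant, model
#'   order), optional N x 9 matrices \code{nu_eff}, \code{a_eff}
#'   (defaulting to zero), and scalars \code{mu_nu}, \code{sigma_nu},
#'   \code{mu_a}, \code{sigma_a}, \code{mu_tau_plus}, \code{sigma_tau_plus},
#'   \code{mu_tau_minus}, \code{sigma_tau_minus}, optional
#'   \code{delta_nu}, \code{delta_a} (length 9, default zero),
#'   \code{sigma_nu_eff}, \code{sigma_a_eff}.
#' @return Scalar log density (\code{-Inf} outside the domain).
#' @export
model_log_density <- function(model, state) {
  N <- length(model$person_ids)
  ne <- state$nu_eff
  ae <- state$a_eff
  if (is.null(ne)) ne <- matrix(0, N, 9)
  if (is.null(ae)) ae <- matrix(0, N, 9)
  dnu <- if (is.null(state$delta_nu)) rep(0, 9) else state$delta_nu
  da <- if (is.null(state$delta_a)) rep(0, 9) else state$delta_a
  sne <- if (is.null(state$sigma_nu_eff)) 0.1 else state$sigma_nu_eff
  sae <- if (is.null(state$sigma_a_eff)) 0.1 else state$sigma_a_eff
  if (any(c(state$sigma_nu, state$sigma_a, state$sigma_tau_plus,
            state$sigma_tau_minus, sne, sae) <= 0) ||
      state$mu_a <= 0 || state$mu_tau_plus <= 0 || state$mu_tau_minus <= 0 ||
      any(state$a <= 0) || any(state$tau_plus < 0) || any(state$tau_minus < 0)) {
    return(-Inf)
  }
  effs10 <- function(m) cbind(m, -rowSums(m))
  ne10 <- effs10(ne)
  ae10 <- effs10(ae)
  p <- model$person_index + 1L
  c10 <- model$cond_index + 1L
  v <- state$nu[p] + ne10[cbind(p, c10)]
  a <- state$a[p] + ae10[cbind(p, c10)]
  tau <- ifelse(model$correct == 1L, state$tau_plus[p], state$tau_minus[p])
  td <- model$rt - tau
  if (any(td <= 0) || any(a <= 0)) return(-Inf)
  # upper boundary for correct responses via reflection at w = 0.5
  ll <- sum(vapply(seq_along(td), function(i) {
    wfpt_logpdf_cpp(td[i], if (model$correct[i] == 1L) -v[i] else v[i],
                    a[i], 0.5, FALSE, 1e-9)
  }, numeric(1)))
  pr <- model$priors
  lhn <- function(x, scale) log(2) + dnorm(x, 0, scale, log = TRUE)
  lp <- sum(dnorm(state$nu, state$mu_nu, state$sigma_nu, log = TRUE)) +
    sum(dnorm(state$a, state$mu_a, state$sigma_a, log = TRUE)) +
    sum(dnorm(state$tau_plus, state$mu_tau_plus, state$sigma_tau_plus,
              log = TRUE)) +
    sum(dnorm(state$tau_minus, state$mu_tau_minus, state$sigma_tau_minus,
              log = TRUE)) +
    sum(dnorm(t(ne), dnu, sne, log = TRUE)) +
    sum(dnorm(t(ae), da, sae, log = TRUE)) +
    dnorm(state$mu_nu, pr$mu_nu_mean, pr$mu_nu_sd, log = TRUE) +
    dnorm(state$mu_a, pr$mu_a_mean, pr$mu_a_sd, log = TRUE) +
    dnorm(state$mu_tau_plus, pr$mu_tau_mean, pr$mu_tau_sd, log = TRUE) +
    dnorm(state$mu_tau_minus, pr$mu_tau_mean, pr$mu_tau_sd, log = TRUE) +
    sum(dnorm(dnu, 0, pr$delta_nu_sd, log = TRUE)) +
    sum(dnorm(da, 0, pr$delta_a_sd, log = TRUE)) +
    lhn(state$sigma_nu, pr$sigma_nu_scale) +
    lhn(state$sigma_a, pr$sigma_a_scale) +
    lhn(state$sigma_tau_plus, pr$sigma_tau_scale) +
    lhn(state$sigma_tau_minus, pr$sigma_tau_scale) +
    lhn(sne, pr$sigma_nu_eff_scale) + lhn(sae, pr$sigma_a_eff_scale)
  ll + lp
}

# closed-form-ish starting values (EZ-style moment matching per person)
ez_init <- function(model) {
  N <- length(model$person_ids)
  nu0 <- a0 <- tp0 <- tm0 <- numeric(N)
  for (p in seq_len(N)) {
    sel <- model$person_index == (p - 1L)
    rt <- model$rt[sel]
    ok <- model$correct[sel] == 1L
    n <- sum(sel)
    pc <- min(max((sum(ok) + 0.5) / (n + 1), 0.55), 0.98)
    vrt <- var(rt[ok])
    if (!is.finite(vrt) || vrt <= 0) vrt <- 0.05
    L <- qlogis(pc)
    x <- L * (L * pc^2 - L * pc + pc - 0.5) / vrt
    v <- sign(pc - 0.5) * abs(x)^(1 / 4)
    nu0[p] <- min(max(v, 0.5), 4.5)
    a0[p] <- min(max(L / nu0[p], 0.8), 4)
    tp0[p] <- 0.9 * min(rt[ok])
    tm0[p] <- if (any(!ok)) 0.9 * min(rt[!ok]) else tp0[p]
  }
  list(nu = nu0, a = a0, tau_plus = tp0, tau_minus = tm0,
       mu_nu = mean(nu0), mu_a = mean(a0),
       mu_tau_plus = max(mean(tp0), 0.05),
       mu_tau_minus = max(mean(tm0), 0.05))
}

hier_par_names <- function(person_ids) {
  c("mu_nu", "sigma_nu", "mu_a", "sigma_a",
    "mu_tau_plus", "sigma_tau_plus", "mu_tau_minus", "sigma_tau_minus",
    paste0("delta_nu[", 1:9, "]"), "sigma_nu_eff",
    paste0("delta_a[", 1:9, "]"), "sigma_a_eff",
    as.vector(t(outer(person_ids, c("nu", "a", "tau_plus", "tau_minus"),
                      function(id, par) paste0(par, "[", id, "]")))),
    as.vector(t(outer(person_ids, 1:9,
                      function(id, c) paste0("nu_eff[", id, ",", c, "]")))),
    as.vector(t(outer(person_ids, 1:9,
                      function(id, c) paste0("a_eff[", id, ",", c, "]")))))
}

#' Sample the hierarchical model by MCMC
#'
#' Runs \code{n_chains} independent chains of an adaptive
#' Metropolis-within-Gibbs sampler (random-walk proposals for every
#' parameter with a trial likelihood, conjugate draws for group means,
#' log-scale random walks for group spreads; proposal scales adapt only
#' during burn-in). Chains are seeded deterministically from \code{seed},
#' so the same seed yields bitwise-identical draws.
#'
#' @param model A \code{\link{build_model}} object.
#' @param n_chains Number of chains (default 4).
#' @param n_iter Total iterations per chain (default 6000).
#' @param n_burnin Burn-in iterations discarded per chain (default 1000).
#' @param seed Integer seed.
#' @return An object of class \code{ddm_fit}: an iteration x chain x
#'   parameter draws array plus metadata (\code{n_chains}, \code{n_iter},
#'   \code{n_burnin}, \code{seed}, \code{person_ids}).
#' @export
run_mcmc <- function(model, n_chains = 4, n_iter = 6000, n_burnin = 1000,
                     seed = 1) {
  stopifnot(inherits(model, "ddm_model"), n_burnin < n_iter)
  persons <- model$person_ids
  pn <- hier_par_names(persons)
  keep <- n_iter - n_burnin
  draws <- array(NA_real_, dim = c(keep, n_chains, length(pn)),
                 dimnames = list(NULL, NULL, pn))
  for (ch in seq_len(n_chains)) {
    set.seed(seed + ch - 1L)
    init <- ez_init(model)
    res <- run_hier_ddm_chain_cpp(model$rt, model$correct, model$cond_index,
                              model$person_index, length(persons),
                              init, model$priors,
                              as.integer(n_iter), as.integer(n_burnin))
    draws[, ch, ] <- res$draws
  }
  structure(list(draws = draws, parameters = pn,
                 n_chains = n_chains, n_iter = n_iter, n_burnin = n_burnin,
                 seed = seed, person_ids = persons,
                 conditions = model$spec$conditions,
                 excluded_ids = model$excluded_ids),
            class = "ddm_fit")
}

#' @export
print.ddm_fit <- function(x, ...) {
  cat(sprintf(
    "Hierarchical diffusion fit: %d chains x %d retained draws, %d parameters, %d participants\n",
    x$n_chains, dim(x$draws)[1], length(x$parameters), length(x$person_ids)))
  invisible(x)
}

#' Extract draws of one parameter
#'
#' @param fit A \code{\link{run_mcmc}} result.
#' @param parameter Parameter name, e.g. \code{"mu_nu"} or
#'   \code{"nu[P001]"}.
#' @return Iteration x chain matrix of draws.
#' @export
draws_of <- function(fit, parameter) {
  if (!parameter %in% fit$parameters) {
    stop("draws_of: unknown parameter '", parameter, "'", call. = FALSE)
  }
  fit$draws[, , parameter, drop = TRUE]
}

#' Person-level posterior medians
#'
#' Extracts, per participant, the posterior medians (across all chains and
#' retained iterations) of the drift intercept, boundary intercept and
#' correct-response non-decision time — the quantities carried into the
#' stability analyses. The error non-decision time median is retained in
#' the returned table for bookkeeping but is excluded from downstream
#' stability analyses by the pipeline. Participants that were dropped
#' from the fit appear with \code{NA} medians.
#'
#' @param fit A \code{\link{run_mcmc}} result.
#' @param all_ids Optional full participant id vector; ids absent from the
#'   fit get missing-value rows.
#' @return A data.frame: \code{participant_id}, \code{nu}, \code{a},
#'   \code{tau_plus}, \code{tau_minus}.
#' @export
extract_person_medians <- function(fit, all_ids = NULL) {
  ids <- if (is.null(all_ids)) fit$person_ids else all_ids
  med1 <- function(par, id) {
    if (!par %in% fit$parameters) return(NA_real_)
    median(fit$draws[, , par])
  }
  out <- data.frame(participant_id = ids,
                    nu = NA_real_, a = NA_real_,
                    tau_plus = NA_real_, tau_minus = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    id <- ids[i]
    if (!id %in% fit$person_ids) next
    out$nu[i] <- med1(paste0("nu[", id, "]"))
    out$a[i] <- med1(paste0("a[", id, "]"))
    out$tau_plus[i] <- med1(paste0("tau_plus[", id, "]"))
    out$tau_minus[i] <- med1(paste0("tau_minus[", id, "]"))
  }
  out
}
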