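#' @useDynLib ddmlong, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats approx median quantile rnorm runif sd cor var dnorm
#'   dcauchy dt qnorm qlogis rbinom rgamma rWishart integrate setNames
#'   complete.cases
#' @importFrom utils write.csv read.csv combn
NULL

# Diffusion coefficient convention. All drift rates, boundary separations
# and the parameter magnitudes used throughout the package assume a unit
# diffusion coefficient (sigma = 1, evidence / sqrt(s)).
DDM_SIGMA <- 1

# decision times below this are clamped by the simulator (s)
MIN_DECISION_TIME <- 1e-4

#' Diffusion model parameters for one person (or group) in one condition
#'
#' Bundles the core Wiener diffusion parameters under the unit-diffusion
#' scale convention: drift rate \eqn{\nu} (evidence/s), boundary separation
#' \eqn{a} (evidence units), relative starting point \eqn{z_{rel} = z/a},
#' and two non-decision times — \code{ndt_correct} (\eqn{\tau^+}) added to
#' correct decision times and \code{ndt_error} (\eqn{\tau^-}) added to
#' error decision times. The error non-decision time absorbs the time
#' taken to correct an erroneous response when tasks record only the
#' corrected response. Inter-trial variabilities are identically zero and
#' are not represented.
#'
#' @param drift Drift rate (may be negative).
#' @param boundary Boundary separation, must be positive.
#' @param z_rel Relative starting point in (0, 1); 0.5 when the boundaries
#'   code correct versus error responses.
#' @param ndt_correct Non-decision time for correct responses (s), >= 0.
#' @param ndt_error Non-decision time for error responses (s), >= 0. Not
#'   required to exceed \code{ndt_correct}.
#' @return An object of class \code{ddm_parameters}.
#' @examples
#' p <- ddm_parameters(drift = 2, boundary = 2, ndt_correct = 0.43)
#' choice_probability(p)
#' @export
ddm_parameters <- function(drift, boundary, z_rel = 0.5,
                           ndt_correct = 0, ndt_error = ndt_correct) {
  p <- structure(
    list(drift = drift, boundary = boundary, z_rel = z_rel,
         ndt_correct = ndt_correct, ndt_error = ndt_error,
         sigma = DDM_SIGMA),
    class = "ddm_parameters")
  validate_ddm_parameters(p)
  p
}

validate_ddm_parameters <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (f in c("drift", "boundary", "z_rel", "ndt_correct", "ndt_error")) {
    if (!num1(p[[f]])) {
      stop("ddm_parameters: field '", f, "' must be a finite numeric scalar",
           call. = FALSE)
    }
  }
  if (p$boundary <= 0) {
    stop("ddm_parameters: boundary separation must be > 0 (got ",
         p$boundary, ")", call. = FALSE)
  }
  if (p$z_rel <= 0 || p$z_rel >= 1) {
    stop("ddm_parameters: relative starting point must lie strictly in ",
         "(0, 1) (got ", p$z_rel, ")", call. = FALSE)
  }
  if (p$ndt_correct < 0 || p$ndt_error < 0) {
    stop("ddm_parameters: non-decision times must be >= 0", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.ddm_parameters <- function(x, ...) {
  cat(sprintf(
    "Wiener diffusion parameters (sigma = 1):\n  drift %.4g  boundary %.4g  z_rel %.3g  ndt+ %.4g s  ndt- %.4g s\n",
    x$drift, x$boundary, x$z_rel, x$ndt_correct, x$ndt_error))
  invisible(x)
}

#' First-passage-time density of the Wiener diffusion
#'
#' Defective density of absorption at the chosen boundary at decision time
#' \code{t} (the non-decision times in \code{params} are not added; pass
#' decision times). Integrating the density over \eqn{(0, \infty)} gives
#' the probability of absorption at that boundary. Evaluation switches
#' between the small-time and large-time series expansions, using
#' whichever needs fewer terms at each time, with truncation set for an
#' absolute error of about \code{1e-7}.
#'
#' @param t Vector of decision times (s), all > 0.
#' @param params A \code{\link{ddm_parameters}} object.
#' @param boundary \code{"upper"} (correct response, by convention) or
#'   \code{"lower"} (error).
#' @param log If \code{TRUE} return the log density.
#' @return Numeric vector of (log) densities, in 1/s.
#' @examples
#' p <- ddm_parameters(1, 1.5, ndt_correct = 0.4)
#' ts <- seq(0.05, 3, by = 0.05)
#' d <- wfpt_density(ts, p)
#' @export
wfpt_density <- function(t, params, boundary = c("upper", "lower"),
                         log = FALSE) {
  boundary <- match.arg(boundary)
  validate_ddm_parameters(params)
  if (!is.numeric(t) || any(!is.finite(t))) {
    stop("wfpt_density: t must be finite numeric", call. = FALSE)
  }
  if (any(t <= 0)) {
    stop("wfpt_density: decision times must be > 0", call. = FALSE)
  }
  lp <- wfpt_logpdf_cpp(t, params$drift, params$boundary, params$z_rel,
                        boundary == "upper", 1e-10)
  if (log) lp else exp(lp)
}

#' Probability of absorption at a boundary
#'
#' Closed form for the probability that the diffusion is absorbed at the
#' upper (correct) boundary:
#' \deqn{P(upper) = \frac{1 - e^{-2 \nu z}}{1 - e^{-2 \nu a}}}
#' with \eqn{z = z_{rel} a} and unit diffusion coefficient; the driftless
#' limit is \eqn{z/a = z_{rel}}. The lower-boundary probability is its
#' complement.
#'
#' @inheritParams wfpt_density
#' @return Probability in \eqn{[0, 1]}.
#' @export
choice_probability <- function(params, boundary = c("upper", "lower")) {
  boundary <- match.arg(boundary)
  validate_ddm_parameters(params)
  v <- params$drift
  a <- params$boundary
  z <- params$z_rel * a
  if (abs(v) < 1e-10) {
    p_up <- params$z_rel
  } else {
    # expm1 keeps the ratio accurate for small drifts; for strongly
    # negative exponents both terms saturate at -1 harmlessly
    p_up <- expm1(-2 * v * z) / expm1(-2 * v * a)
  }
  p_up <- min(max(p_up, 0), 1)
  if (boundary == "upper") p_up else 1 - p_up
}

# Inverse-CDF tables for the two boundaries of one parameter set.
# Densities come from the series expansion on a log-spaced decision-time
# grid; the grid upper end is extended until the total absorbed mass is
# within 1e-6 of 1.
wfpt_cdf_grid <- function(params, n_grid = 1024L, tmax0 = NULL) {
  a <- params$boundary
  tmax <- if (is.null(tmax0)) max(4 * a^2, 2) else tmax0
  repeat {
    tg <- exp(seq(log(MIN_DECISION_TIME), log(tmax), length.out = n_grid))
    du <- wfpt_density(tg, params, "upper")
    dl <- wfpt_density(tg, params, "lower")
    dt_ <- diff(tg)
    cup <- c(0, cumsum((du[-1] + du[-n_grid]) / 2 * dt_))
    clo <- c(0, cumsum((dl[-1] + dl[-n_grid]) / 2 * dt_))
    tot <- cup[n_grid] + clo[n_grid]
    if (tot > 1 - 1e-6 || tmax >= 60) break
    tmax <- tmax * 2
  }
  list(t = tg, cdf_upper = cup, cdf_lower = clo,
       p_upper = cup[n_grid], p_lower = clo[n_grid])
}

#' Simulate two-choice trials from the diffusion model
#'
#' Draws first-passage times by inverse-CDF sampling on a cached
#' density-implied grid per parameter set. The observed response time is
#' the decision time plus \code{ndt_correct} when the upper (correct)
#' boundary is hit and plus \code{ndt_error} otherwise. Decision times
#' below 0.1 ms are clamped to 0.1 ms. Reproducible under
#' \code{set.seed()}.
#'
#' @param params A \code{\link{ddm_parameters}} object.
#' @param n Number of trials.
#' @param n_grid Resolution of the cached inverse-CDF grid.
#' @return A data.frame with columns \code{rt} (s) and \code{correct}
#'   (0/1; 1 means the upper boundary was hit).
#' @examples
#' set.seed(1)
#' tr <- simulate_trials(ddm_parameters(2, 2, ndt_correct = 0.4), 100)
#' mean(tr$correct)
#' @export
simulate_trials <- function(params, n, n_grid = 1024L) {
  validate_ddm_parameters(params)
  if (n == 0) return(data.frame(rt = numeric(0), correct = integer(0)))
  grid <- wfpt_cdf_grid(params, n_grid = n_grid)
  p_up <- choice_probability(params, "upper")
  correct <- as.integer(runif(n) < p_up)
  rt <- numeric(n)
  for (b in c(1L, 0L)) {
    idx <- which(correct == b)
    if (!length(idx)) next
    cdf <- if (b == 1L) grid$cdf_upper else grid$cdf_lower
    pb <- if (b == 1L) grid$p_upper else grid$p_lower
    u <- runif(length(idx)) * pb
    # strictly increasing sub-grid for interpolation
    keep <- c(TRUE, diff(cdf) > 0)
    td <- approx(cdf[keep], grid$t[keep], xout = u, rule = 2)$y
    td <- pmax(td, MIN_DECISION_TIME)
    tau <- if (b == 1L) params$ndt_correct else params$ndt_error
    rt[idx] <- td + tau
  }
  data.frame(rt = rt, correct = correct)
}

#' Effect-coded condition structure
#'
#' Sum-to-zero (effect-coded) condition effects on drift rate and boundary
#' separation for the ten task conditions (five traits crossed with
#' congruent/incongruent block pairing). Under effect coding the intercept
#' is the grand mean across conditions and the effects of all conditions
#' sum to zero per parameter.
#'
#' @param labels Character vector of exactly 10 condition labels.
#' @param drift_effects,boundary_effects Numeric vectors of length 10
#'   summing to zero (tolerance 1e-8), named or in label order.
#' @return An object of class \code{condition_effects}.
#' @export
condition_effects <- function(labels = default_condition_labels(),
                              drift_effects = rep(0, 10),
                              boundary_effects = rep(0, 10)) {
  if (length(labels) != 10L || anyDuplicated(labels)) {
    stop("condition_effects: exactly 10 distinct condition labels required",
         call. = FALSE)
  }
  chk <- function(x, nm) {
    if (length(x) != 10L) {
      stop("condition_effects: ", nm, " must have length 10", call. = FALSE)
    }
    if (abs(sum(x)) > 1e-8) {
      stop("condition_effects: ", nm, " must sum to zero (effect coding)",
           call. = FALSE)
    }
    setNames(as.numeric(x), labels)
  }
  structure(
    list(labels = labels,
         drift_effects = chk(drift_effects, "drift_effects"),
         boundary_effects = chk(boundary_effects, "boundary_effects")),
    class = "condition_effects")
}

#' Default condition labels: five Big Five traits crossed with block
#' congruency.
#' @return Character vector of 10 labels, \code{"<trait>:<congruency>"}.
#' @export
default_condition_labels <- function() {
  traits <- c("openness", "conscientiousness", "extraversion",
              "agreeableness", "neuroticism")
  as.vector(outer(traits, c("congruent", "incongruent"),
                  function(a, b) paste(a, b, sep = ":")))
}

#' Apply a condition's effects to base parameters
#'
#' Adds the condition-specific drift and boundary effects to the base
#' (intercept) parameters; starting point and non-decision times are
#' unaffected by condition. The result is re-validated, so a condition
#' driving the boundary separation non-positive raises an error naming the
#' condition.
#'
#' @param base A \code{\link{ddm_parameters}} object (intercepts).
#' @param effects A \code{\link{condition_effects}} object.
#' @param condition One of the effect object's labels.
#' @return A \code{\link{ddm_parameters}} object for that condition.
#' @export
apply_condition_effects <- function(base, effects, condition) {
  validate_ddm_parameters(base)
  if (!inherits(effects, "condition_effects")) {
    stop("apply_condition_effects: 'effects' must be a condition_effects object",
         call. = FALSE)
  }
  if (!condition %in% effects$labels) {
    stop("apply_condition_effects: unknown condition '", condition, "'",
         call. = FALSE)
  }
  a_new <- base$boundary + effects$boundary_effects[[condition]]
  if (a_new <= 0) {
    stop("apply_condition_effects: condition '", condition,
         "' yields non-positive boundary separation (", a_new, ")",
         call. = FALSE)
  }
  ddm_parameters(drift = base$drift + effects$drift_effects[[condition]],
                 boundary = a_new,
                 z_rel = base$z_rel,
                 ndt_correct = base$ndt_correct,
                 ndt_error = base$ndt_error)
}
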