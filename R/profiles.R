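# Profile (q) stability: z-standardize person-level posterior medians per
# parameter, then correlate each person's 3-parameter profile across
# occasion pairs. Plus the dropout Bayes-factor t-test.

#' z-standardize person-level medians
#'
#' Standardizes each parameter column to mean 0 and SD 1 across
#' participants. By default standardization is done separately per time
#' point (removing mean-level change, so profiles encode relative
#' standing); \code{scope = "pooled"} standardizes across the pooled
#' person x time matrix instead. Missing values stay missing.
#'
#' @param medians Long table: \code{participant_id}, \code{time_point},
#'   \code{nu}, \code{a}, \code{tau_plus}.
#' @param scope \code{"per_time_point"} (default) or \code{"pooled"}.
#' @return The table with parameter columns replaced by z-scores.
#' @export
standardize_profiles <- function(medians,
                                 scope = c("per_time_point", "pooled")) {
  scope <- match.arg(scope)
  pars <- c("nu", "a", "tau_plus")
  out <- medians
  zfun <- function(x, label) {
    obs <- x[is.finite(x)]
    if (length(obs) < 3) {
      stop("standardize_profiles: fewer than 3 observed values for ", label,
           call. = FALSE)
    }
    if (sd(obs) == 0) {
      stop("standardize_profiles: zero variance for ", label, call. = FALSE)
    }
    (x - mean(obs)) / sd(obs)
  }
  for (p in pars) {
    if (scope == "pooled") {
      out[[p]] <- zfun(out[[p]], p)
    } else {
      for (tp in unique(out$time_point)) {
        sel <- out$time_point == tp
        out[[p]][sel] <- zfun(out[[p]][sel],
                              paste0(p, " at time point ", tp))
      }
    }
  }
  out
}

#' Within-person profile (q) correlations across an occasion pair
#'
#' For each participant with all three standardized parameters observed
#' at both occasions, the Pearson correlation over the three paired
#' (z-drift, z-boundary, z-non-decision) values. Zero-variance profiles
#' yield a missing q and are counted.
#'
#' @param z Standardized table from \code{\link{standardize_profiles}}.
#' @param t1,t2 Occasion indices.
#' @return List: \code{records} (participant, t1, t2, q) and
#'   \code{summary} (mean, SD, median, N, n_zero_variance).
#' @export
q_profile_correlations <- function(z, t1, t2) {
  pars <- c("nu", "a", "tau_plus")
  w1 <- z[z$time_point == t1, c("participant_id", pars)]
  w2 <- z[z$time_point == t2, c("participant_id", pars)]
  ids <- intersect(w1$participant_id, w2$participant_id)
  qv <- rep(NA_real_, length(ids))
  n_zero <- 0L
  for (i in seq_along(ids)) {
    p1 <- as.numeric(w1[match(ids[i], w1$participant_id), pars])
    p2 <- as.numeric(w2[match(ids[i], w2$participant_id), pars])
    if (anyNA(p1) || anyNA(p2)) next
    if (sd(p1) == 0 || sd(p2) == 0) { n_zero <- n_zero + 1L; next }
    qv[i] <- cor(p1, p2)
  }
  ok <- is.finite(qv)
  list(records = data.frame(participant_id = ids, t1 = t1, t2 = t2, q = qv),
       summary = data.frame(t1 = t1, t2 = t2,
                            mean = mean(qv[ok]), sd = sd(qv[ok]),
                            median = median(qv[ok]), n = sum(ok),
                            n_zero_variance = n_zero))
}

#' Summary of q correlations for all occasion pairs
#'
#' @param z Standardized table from \code{\link{standardize_profiles}}.
#' @return data.frame with one row per occasion pair (mean, SD, median,
#'   N).
#' @export
q_profile_summary <- function(z) {
  tps <- sort(unique(z$time_point))
  pairs <- t(combn(tps, 2))
  do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    q_profile_correlations(z, pairs[i, 1], pairs[i, 2])$summary
  }))
}

#' Two-sample Bayes-factor t-test (dropout analysis)
#'
#' Default-prior Bayes factor for a two-sample comparison: a zero-centred
#' Cauchy prior with scale \eqn{\sqrt{2}/2} on the standardized effect
#' size, evaluated through the standard scale-mixture (inverse-gamma on
#' g) integral representation. Used to ask whether persons missing at
#' any later occasion differ from complete cases on a parameter.
#'
#' @param x,y Numeric vectors (e.g. dropouts vs completers), each n >= 2.
#' @param rscale Cauchy prior scale (default \code{sqrt(2)/2}).
#' @return List: \code{bf10}, \code{t}, \code{df}, \code{n1}, \code{n2}.
#' @export
dropout_bayes_t_test <- function(x, y, rscale = sqrt(2) / 2) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) {
    stop("dropout_bayes_t_test: both groups need n >= 2", call. = FALSE)
  }
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / df
  if (sp2 <= 0) stop("dropout_bayes_t_test: zero pooled variance",
                     call. = FALSE)
  neff <- n1 * n2 / (n1 + n2)
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 / neff)
  # marginal likelihood under H1: integral over g with
  # g ~ InverseGamma(1/2, rscale^2/2)
  integrand <- function(g) {
    (1 + neff * g)^(-1 / 2) *
      (1 + tstat^2 / ((1 + neff * g) * df))^(-(df + 1) / 2) *
      (rscale^2 / 2)^(1 / 2) / gamma(1 / 2) * g^(-3 / 2) *
      exp(-rscale^2 / (2 * g))
  }
  m1 <- integrate(integrand, 0, Inf, rel.tol = 1e-9)$value
  m0 <- (1 + tstat^2 / df)^(-(df + 1) / 2)
  list(bf10 = m1 / m0, t = tstat, df = df, n1 = n1, n2 = n2)
}
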