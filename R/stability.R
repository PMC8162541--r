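# Rank-order stability (Bayesian correlations with a uniform prior),
# highest density intervals, and mean-level comparison of group-level
# posteriors across occasions.

#' Bayesian correlation with a uniform prior
#'
#' Posterior for the population correlation \eqn{\rho} of paired
#' observations under a uniform prior on (-1, 1), computed by numerical
#' integration of the sample-correlation likelihood
#' \eqn{p(r \mid \rho) \propto (1-\rho^2)^{(n-1)/2} (1-\rho r)^{(3-2n)/2}}
#' on a fine grid. The Bayes factor against \eqn{\rho = 0} is the
#' Savage-Dickey density ratio at zero (prior density 1/2).
#'
#' @param x,y Paired numeric vectors; pairs with missing values are
#'   dropped; at least 3 complete pairs required.
#' @param n_grid Grid resolution for the quadrature.
#' @return Object of class \code{bayes_cor}: posterior mean of rho, 95%
#'   central credible interval, \code{bf10}, \code{n}, and the observed
#'   sample correlation \code{r}.
#' @export
bayesian_correlation <- function(x, y, n_grid = 4001L) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("bayesian_correlation: need at least 3 complete pairs",
                  call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("bayesian_correlation: zero variance makes the correlation undefined",
         call. = FALSE)
  }
  r <- cor(x, y)
  rho <- seq(-1 + 1e-9, 1 - 1e-9, length.out = n_grid)
  loglik <- (n - 1) / 2 * log1p(-rho^2) + (3 / 2 - n) * log1p(-rho * r)
  loglik <- loglik - max(loglik)
  w <- exp(loglik)
  dz <- rho[2] - rho[1]
  norm <- sum(w) * dz
  post <- w / norm
  pmean <- sum(rho * post) * dz
  cdf <- cumsum(post) * dz
  ci <- c(rho[which(cdf >= 0.025)[1]], rho[which(cdf >= 0.975)[1]])
  post0 <- approx(rho, post, xout = 0)$y
  bf10 <- 0.5 / post0
  structure(list(mean = pmean, ci = ci, bf10 = bf10, n = n, r = r),
            class = "bayes_cor")
}

#' @export
print.bayes_cor <- function(x, ...) {
  bf <- if (x$bf10 > 999) ">999" else sprintf("%.2f", x$bf10)
  cat(sprintf("rho = %.2f [%.2f-%.2f], BF10 = %s, n = %d\n",
              x$mean, x$ci[1], x$ci[2], bf, x$n))
  invisible(x)
}

#' Rank-order stability matrix
#'
#' Bayesian correlations of one parameter's person-level posterior
#' medians across all six occasion pairs, on pairwise-complete cases,
#' optionally restricted to one subgroup. Pairs with fewer than 3
#' complete cases yield missing cells (logged); cells with fewer than 30
#' cases carry a small-sample flag.
#'
#' @param medians Long table with columns \code{participant_id},
#'   \code{time_point}, and the parameter columns (\code{nu}, \code{a},
#'   \code{tau_plus}); optionally \code{subgroup}.
#' @param parameter One of \code{"nu"}, \code{"a"}, \code{"tau_plus"}.
#' @param subgroup Optional subgroup value to filter on.
#' @param small_n Threshold below which a cell is flagged small-sample.
#' @return data.frame with one row per occasion pair: \code{t1},
#'   \code{t2}, \code{rho}, \code{ci_lower}, \code{ci_upper},
#'   \code{bf10}, \code{n}, \code{small_n_flag}.
#' @export
rank_order_matrix <- function(medians, parameter = c("nu", "a", "tau_plus"),
                              subgroup = NULL, small_n = 30L) {
  parameter <- match.arg(parameter)
  if (!is.null(subgroup)) {
    medians <- medians[medians$subgroup %in% subgroup, , drop = FALSE]
  }
  tps <- sort(unique(medians$time_point))
  pairs <- t(combn(tps, 2))
  wide <- tapply(medians[[parameter]],
                 list(medians$participant_id, medians$time_point),
                 identity)
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    t1 <- pairs[i, 1]; t2 <- pairs[i, 2]
    x <- wide[, as.character(t1)]; y <- wide[, as.character(t2)]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3) {
      rows[[i]] <- data.frame(t1 = t1, t2 = t2, rho = NA_real_,
                              ci_lower = NA_real_, ci_upper = NA_real_,
                              bf10 = NA_real_, n = sum(ok),
                              small_n_flag = TRUE)
      next
    }
    bc <- bayesian_correlation(x[ok], y[ok])
    rows[[i]] <- data.frame(t1 = t1, t2 = t2, rho = bc$mean,
                            ci_lower = bc$ci[1], ci_upper = bc$ci[2],
                            bf10 = bc$bf10, n = bc$n,
                            small_n_flag = bc$n < small_n)
  }
  do.call(rbind, rows)
}

#' Highest density interval of a sample
#'
#' Shortest interval containing the target posterior mass, by the
#' sorted-window method; width ties are broken to the leftmost window.
#'
#' @param samples Numeric vector of at least 100 draws.
#' @param mass Target mass (default 0.95).
#' @return Numeric vector \code{c(lower, upper)}.
#' @export
hdi <- function(samples, mass = 0.95) {
  samples <- samples[is.finite(samples)]
  n <- length(samples)
  if (n < 100) stop("hdi: need at least 100 samples", call. = FALSE)
  s <- sort(samples)
  k <- ceiling(mass * n)
  if (k >= n) return(c(s[1], s[n]))
  widths <- s[(k + 1):n] - s[seq_len(n - k)]
  i <- which.min(widths)  # which.min returns the first (leftmost) minimum
  c(s[i], s[i + k])
}

#' Mean-level comparison of group-level posteriors across occasions
#'
#' For every pair of occasions, reports both 95% highest density
#' intervals of the group-level parameter draws, whether they overlap,
#' and the posterior mean difference.
#'
#' @param draws_by_time List of numeric draw vectors, one per occasion
#'   (group-level draws pooled over chains).
#' @param mass HDI mass (default 0.95).
#' @return data.frame with one row per occasion pair.
#' @export
mean_level_comparison <- function(draws_by_time, mass = 0.95) {
  tps <- seq_along(draws_by_time)
  his <- lapply(draws_by_time, hdi, mass = mass)
  pairs <- t(combn(tps, 2))
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    t1 <- pairs[i, 1]; t2 <- pairs[i, 2]
    h1 <- his[[t1]]; h2 <- his[[t2]]
    overlap <- h1[1] <= h2[2] && h2[1] <= h1[2]
    data.frame(t1 = t1, t2 = t2,
               hdi1_lower = h1[1], hdi1_upper = h1[2],
               hdi2_lower = h2[1], hdi2_upper = h2[2],
               overlap = overlap,
               mean_difference = mean(draws_by_time[[t2]]) -
                 mean(draws_by_time[[t1]]))
  })
  do.call(rbind, rows)
}
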