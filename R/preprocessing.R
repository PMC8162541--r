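# Pre-fit exclusion steps with full exclusion accounting. The fixed order
# is: non-recorded trials -> RT window -> low-accuracy participants ->
# warm-up trials; every step logs counts by reason.

#' Keep trials inside the response-time window
#'
#' Retains trials with \code{low <= rt_s <= high}; the bounds themselves
#' are retained (the exclusion reads "below"/"above" as strict). Trials
#' flagged as not recorded must be removed beforehand (see
#' \code{\link{preprocess_trials}}).
#'
#' @param trials Trial table with an \code{rt_s} column.
#' @param low,high Window bounds in seconds (defaults 0.3 and 3.0).
#' @return List: \code{trials} (retained rows) and \code{log} (data.frame
#'   of step, reason, n_excluded, fraction of input).
#' @export
filter_rt_window <- function(trials, low = 0.3, high = 3.0) {
  n <- nrow(trials)
  if (n == 0) {
    return(list(trials = trials,
                log = data.frame(step = "rt_window",
                                 reason = c("rt_too_fast", "rt_too_slow"),
                                 n_excluded = c(0L, 0L), fraction = c(0, 0))))
  }
  if (any(trials$rt_s <= 0)) {
    stop("filter_rt_window: non-positive RTs present", call. = FALSE)
  }
  fast <- trials$rt_s < low
  slow <- trials$rt_s > high
  list(trials = trials[!fast & !slow, , drop = FALSE],
       log = data.frame(step = "rt_window",
                        reason = c("rt_too_fast", "rt_too_slow"),
                        n_excluded = c(sum(fast), sum(slow)),
                        fraction = c(sum(fast) / n, sum(slow) / n)))
}

#' Low-accuracy participant exclusion (3-IQR rule)
#'
#' Excludes participants whose accuracy falls more than three
#' interquartile ranges below the first quartile of the accuracy
#' distribution across participants: cutoff \eqn{Q_1 - 3 \cdot IQR},
#' exclusion strictly below the cutoff. Quartiles use linear
#' interpolation between order statistics (R quantile type 7); the rule
#' is applied independently per time point by the pipeline.
#'
#' @param accuracy Named numeric vector of per-participant accuracies at
#'   one time point (names are participant ids).
#' @param iqr_multiplier Multiplier of the IQR (default 3).
#' @return List: \code{excluded} (ids), \code{cutoff}, \code{q1},
#'   \code{iqr}.
#' @export
exclude_low_accuracy <- function(accuracy, iqr_multiplier = 3) {
  if (length(accuracy) < 4) {
    stop("exclude_low_accuracy: need at least 4 participants for stable quartiles",
         call. = FALSE)
  }
  q <- quantile(accuracy, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  cutoff <- q[1] - iqr_multiplier * iqr
  excluded <- names(accuracy)[accuracy < cutoff]
  list(excluded = if (is.null(excluded)) character(0) else excluded,
       cutoff = cutoff, q1 = q[1], iqr = iqr)
}

#' Remove warm-up trials
#'
#' Drops the first trial of each (participant, time point, block),
#' preferring the \code{warmup_flag} column when present (idempotent on
#' the flag) and falling back to \code{trial_index == min} per block.
#'
#' @param trials Trial table.
#' @return List: \code{trials} without warm-up rows, \code{log}.
#' @export
drop_warmup <- function(trials) {
  n <- nrow(trials)
  if (n == 0) {
    return(list(trials = trials,
                log = data.frame(step = "warmup", reason = "warmup_trial",
                                 n_excluded = 0L, fraction = 0)))
  }
  if ("warmup_flag" %in% names(trials)) {
    drop <- trials$warmup_flag
  } else {
    key <- interaction(trials$participant_id, trials$time_point,
                       trials$block_index, drop = TRUE)
    first <- !duplicated(key)
    drop <- first  # rows arrive in within-block order
  }
  list(trials = trials[!drop, , drop = FALSE],
       log = data.frame(step = "warmup", reason = "warmup_trial",
                        n_excluded = sum(drop), fraction = sum(drop) / n))
}

#' Full preprocessing pipeline for one or more time points
#'
#' Applies, in fixed order: removal of non-recorded trials, the RT window,
#' the per-time-point 3-IQR low-accuracy participant exclusion, and
#' warm-up removal. The participant accuracy entering the 3-IQR rule is
#' computed on recorded trials across all blocks; by default before the
#' RT window is applied (switchable with
#' \code{accuracy_before_rt_filter = FALSE}).
#'
#' @param trials Trial table (may span several time points).
#' @param rt_low,rt_high RT window (s).
#' @param iqr_multiplier IQR multiplier of the accuracy rule.
#' @param accuracy_before_rt_filter Compute the accuracy entering the
#'   exclusion rule before (default) or after RT filtering.
#' @return List: \code{trials} (retained), \code{log} (step-ordered
#'   exclusion log with counts and fractions of the recorded total),
#'   \code{excluded_participants} (per time point), and
#'   \code{excluded_fraction} (trials excluded by the first three steps /
#'   recorded trials).
#' @export
preprocess_trials <- function(trials, rt_low = 0.3, rt_high = 3.0,
                              iqr_multiplier = 3,
                              accuracy_before_rt_filter = TRUE) {
  n0 <- nrow(trials)
  logs <- list()
  nr <- sum(!trials$recorded_flag)
  logs[[1]] <- data.frame(step = "non_recorded", reason = "not_recorded",
                          n_excluded = nr,
                          fraction = if (n0 > 0) nr / n0 else 0)
  rec <- trials[trials$recorded_flag, , drop = FALSE]
  n_rec <- nrow(rec)

  fw <- filter_rt_window(rec, rt_low, rt_high)
  fw$log$fraction <- if (n_rec > 0) fw$log$n_excluded / n_rec else 0
  logs[[2]] <- fw$log

  # accuracy per participant per time point, on recorded trials
  acc_src <- if (accuracy_before_rt_filter) rec else fw$trials
  excluded_participants <- list()
  keep <- fw$trials
  n_acc <- 0L
  for (tp in sort(unique(rec$time_point))) {
    sub <- acc_src[acc_src$time_point == tp, , drop = FALSE]
    acc <- tapply(sub$correct, sub$participant_id, mean)
    res <- exclude_low_accuracy(setNames(as.numeric(acc), names(acc)),
                                iqr_multiplier)
    excluded_participants[[as.character(tp)]] <- res$excluded
    if (length(res$excluded)) {
      sel <- keep$time_point == tp & keep$participant_id %in% res$excluded
      n_acc <- n_acc + sum(sel)
      keep <- keep[!sel, , drop = FALSE]
    }
  }
  logs[[3]] <- data.frame(step = "low_accuracy", reason = "low_accuracy_participant",
                          n_excluded = n_acc,
                          fraction = if (n_rec > 0) n_acc / n_rec else 0)

  wu <- drop_warmup(keep)
  logs[[4]] <- wu$log
  log <- do.call(rbind, logs)
  excl3 <- nr + sum(fw$log$n_excluded) + n_acc
  list(trials = wu$trials, log = log,
       excluded_participants = excluded_participants,
       excluded_fraction = if (n0 > 0) excl3 / n0 else 0)
}
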