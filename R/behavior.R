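#' Binned lick rate
#'
#' Counts licks in fixed bins (100 ms by default) and divides by the bin
#' width to give a rate in Hz.
#'
#' @param lick_times Sorted lick times (s).
#' @param bin_s Bin width (s), default 0.1.
#' @param t_range Optional two-element range (s) the binning should cover;
#'   defaults to `[0, max(lick_times)]` rounded up to a whole bin.
#' @return Data frame with `time_s` (left bin edges) and `rate_hz`.
#' @export
lick_rate <- function(lick_times, bin_s = 0.1, t_range = NULL) {
  if (is.unsorted(lick_times)) stop("lick_times must be sorted")
  if (is.null(t_range)) {
    hi <- if (length(lick_times)) max(lick_times) else bin_s
    t_range <- c(0, ceiling(hi / bin_s) * bin_s)
  }
  edges <- seq(t_range[1], t_range[2], by = bin_s)
  counts <- if (length(lick_times)) {
    tabulate(findInterval(lick_times, edges, left.open = FALSE,
                          rightmost.closed = FALSE),
             nbins = length(edges) - 1)
  } else {
    integer(length(edges) - 1)
  }
  data.frame(time_s = edges[-length(edges)], rate_hz = counts / bin_s)
}

# Mean of a rate trace over the half-open window [a, b), using bins whose
# left edge falls inside the window. Returns NA when no bins are covered.
.rate_window_mean <- function(rate_trace, a, b) {
  sel <- .in_window(rate_trace$time_s, a, b)
  if (!any(sel)) return(NA_real_)
  mean(rate_trace$rate_hz[sel])
}

#' Anticipatory lick rate
#'
#' Mean lick rate during the trace-period second before reward
#' (`[cue + 8, cue + 9)`) minus the mean baseline rate during the second
#' before cue onset (`[cue - 1, cue)`). A positive value indicates the
#' animal licks in anticipation of the reward.
#'
#' @param rate_trace Data frame from [lick_rate()].
#' @param cue_onset_t Cue onset time (s).
#' @param cue_duration_s,trace_s Trial timing (defaults 8 and 1 s).
#' @return Baseline-subtracted rate (Hz), or `NA` with a warning when the
#'   trial is not fully covered (it is dropped).
#' @export
anticipatory_lick_rate <- function(rate_trace, cue_onset_t,
                                   cue_duration_s = 8, trace_s = 1) {
  lo <- cue_onset_t - 1
  hi <- cue_onset_t + cue_duration_s + trace_s
  tmin <- min(rate_trace$time_s)
  tmax <- max(rate_trace$time_s)
  if (lo < tmin || hi > tmax + (rate_trace$time_s[2] - rate_trace$time_s[1])) {
    warning("trial not fully covered by the rate trace; dropped")
    return(NA_real_)
  }
  trace_mean <- .rate_window_mean(rate_trace, cue_onset_t + cue_duration_s, hi)
  base_mean <- .rate_window_mean(rate_trace, lo, cue_onset_t)
  trace_mean - base_mean
}

#' Lick-rate slope over the ramp window
#'
#' OLS slope of the binned lick rate against time over the same 3-8 s
#' window used for the dopamine ramp, for comparability between the
#' behavioral and dopamine ramps.
#'
#' @param rate_trace Data frame from [lick_rate()].
#' @param cue_onset_t Cue onset time (s).
#' @param window Window relative to cue onset (s), half-open.
#' @return Slope in Hz per second.
#' @export
lick_slope <- function(rate_trace, cue_onset_t, window = c(3, 8)) {
  sel <- .in_window(rate_trace$time_s, cue_onset_t + window[1],
                    cue_onset_t + window[2])
  if (sum(sel) < 2) stop("fewer than 2 rate bins in the window")
  .ols_slope(rate_trace$time_s[sel], rate_trace$rate_hz[sel])
}

#' Velocity from uniformly sampled distance
#'
#' First difference of distance divided by the sampling step, aligned to
#' the later sample. Distance must be sampled uniformly (50 ms in the VR
#' task).
#'
#' @param distance Data frame with `time_s` and `distance_cm`.
#' @param expected_dt_s Expected sampling step (s), default 0.05.
#' @param tol_s Tolerated deviation of each step (s).
#' @return Data frame with `time_s` and `velocity_cm_s`.
#' @export
velocity_trace <- function(distance, expected_dt_s = 0.05, tol_s = 1e-6) {
  dts <- diff(distance$time_s)
  if (any(abs(dts - expected_dt_s) > tol_s)) {
    stop("distance samples are not uniform at the expected rate")
  }
  data.frame(time_s = distance$time_s[-1],
             velocity_cm_s = diff(distance$distance_cm) / expected_dt_s)
}

#' Velocity change at trial onset
#'
#' Mean velocity 1-2 s after trial onset minus the mean baseline velocity
#' in the second before onset.
#'
#' @param velocity Data frame from [velocity_trace()].
#' @param trial_onset_t Trial onset time (s).
#' @return Velocity change (cm/s), or `NA` with a warning on incomplete
#'   coverage.
#' @export
onset_velocity_change <- function(velocity, trial_onset_t) {
  t <- velocity$time_s
  if (trial_onset_t - 1 < t[1] || trial_onset_t + 2 > t[length(t)]) {
    warning("onset window outside velocity trace; trial dropped")
    return(NA_real_)
  }
  post <- .in_window(t, trial_onset_t + 1, trial_onset_t + 2)
  pre <- .in_window(t, trial_onset_t - 1, trial_onset_t)
  mean(velocity$velocity_cm_s[post]) - mean(velocity$velocity_cm_s[pre])
}

#' Mean velocity in the second before reward
#'
#' @param velocity Data frame from [velocity_trace()].
#' @param reward_t Reward time (s).
#' @return Mean velocity (cm/s) over `[reward - 1, reward)`, or `NA` with
#'   a warning on incomplete coverage.
#' @export
pre_reward_velocity <- function(velocity, reward_t) {
  t <- velocity$time_s
  if (reward_t - 1 < t[1] || reward_t > t[length(t)] + 0.05) {
    warning("pre-reward window outside velocity trace; trial dropped")
    return(NA_real_)
  }
  sel <- .in_window(t, reward_t - 1, reward_t)
  mean(velocity$velocity_cm_s[sel])
}
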