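#' Scale the isosbestic channel to the signal channel
#'
#' Least-squares fit of the 405 nm (dopamine-independent) channel to the
#' 470 nm (dopamine-dependent) channel: `fitted405 = a * ch405 + c`. The
#' affine form (slope plus intercept) guards against offset differences
#' between channels; set `intercept = FALSE` for a pure scaling.
#'
#' @param ch405,ch470 Numeric vectors of equal length (raw fluorescence).
#' @param intercept Include an intercept term (default `TRUE`).
#' @return Numeric vector `fitted405` with attributes `a` and `c`.
#' @export
fit_isosbestic <- function(ch405, ch470, intercept = TRUE) {
  stopifnot(length(ch405) == length(ch470), length(ch405) >= 2)
  if (stats::sd(ch405) == 0) stop("constant 405 channel: cannot fit")
  if (intercept) {
    v405 <- ch405 - mean(ch405)
    a <- sum(v405 * (ch470 - mean(ch470))) / sum(v405^2)
    cc <- mean(ch470) - a * mean(ch405)
  } else {
    a <- sum(ch405 * ch470) / sum(ch405^2)
    cc <- 0
  }
  fitted <- a * ch405 + cc
  attr(fitted, "a") <- a
  attr(fitted, "c") <- cc
  fitted
}

#' Percentage dF/F from the signal channel and fitted isosbestic
#'
#' `dF/F = (ch470 - fitted405) / fitted405 * 100`, elementwise. Dividing by
#' the fitted isosbestic removes bleaching and motion components shared by
#' the two channels.
#'
#' @param ch470 Signal channel (raw fluorescence).
#' @param fitted405 Fitted isosbestic from [fit_isosbestic()]; must be
#'   positive everywhere.
#' @return Numeric vector of dF/F values in percent.
#' @export
compute_dff <- function(ch470, fitted405) {
  stopifnot(length(ch470) == length(fitted405))
  bad <- which(fitted405 <= 0)
  if (length(bad) > 0) {
    stop(sprintf("nonpositive fitted 405 value at sample index %d", bad[1]))
  }
  as.numeric((ch470 - fitted405) / fitted405 * 100)
}

#' Construct a dF/F trace
#'
#' @param time_s Sample timestamps (s), strictly increasing.
#' @param dff_percent dF/F values (percent), finite.
#' @return A data frame of class `dff_trace`.
#' @export
dff_trace <- function(time_s, dff_percent) {
  stopifnot(length(time_s) == length(dff_percent))
  if (any(diff(time_s) <= 0)) stop("timestamps must be strictly increasing")
  if (any(!is.finite(dff_percent))) stop("dF/F values must be finite")
  structure(
    data.frame(time_s = time_s, dff_percent = dff_percent),
    class = c("dff_trace", "data.frame")
  )
}

#' Event-aligned matrix and mean PSTH
#'
#' Bins the trace into the half-open window `[window[1], window[2])` around
#' each event. Bins that fall outside the recording are `NA` and are
#' ignored by the mean.
#'
#' @param trace A [dff_trace()].
#' @param event_times Event times (s).
#' @param window Two-element numeric window around each event (s).
#' @param bin_s Bin width (s).
#' @return A list: `matrix` (events x bins), `bin_centers_s`, `psth`
#'   (column means ignoring `NA`).
#' @export
event_aligned_matrix <- function(trace, event_times, window, bin_s) {
  if (length(event_times) == 0) stop("empty event list")
  stopifnot(length(window) == 2, window[1] < window[2], bin_s > 0)
  edges <- seq(window[1], window[2], by = bin_s)
  n_bins <- length(edges) - 1
  m <- matrix(NA_real_, nrow = length(event_times), ncol = n_bins)
  for (i in seq_along(event_times)) {
    rel <- trace$time_s - event_times[i]
    for (bn in seq_len(n_bins)) {
      sel <- rel >= edges[bn] & rel < edges[bn + 1]
      if (any(sel)) m[i, bn] <- mean(trace$dff_percent[sel])
    }
  }
  list(matrix = m,
       bin_centers_s = edges[-length(edges)] + bin_s / 2,
       psth = colMeans(m, na.rm = TRUE))
}

#' Onset peak response
#'
#' Maximum dF/F in the second after the event minus the mean dF/F in the
#' second before it. Returns `NA` with a warning when the +/-1 s window is
#' not fully covered by the recording (the trial is dropped, not an error).
#'
#' @param trace A [dff_trace()].
#' @param event_t Event time (s).
#' @return Peak response (percent dF/F), or `NA`.
#' @export
onset_peak_response <- function(trace, event_t) {
  t <- trace$time_s
  if (event_t - 1 < t[1] || event_t + 1 > t[length(t)]) {
    warning("onset window outside recording; trial dropped")
    return(NA_real_)
  }
  post <- .in_window(t, event_t, event_t + 1)
  pre <- .in_window(t, event_t - 1, event_t)
  max(trace$dff_percent[post]) - mean(trace$dff_percent[pre])
}

#' Within-trial ramp slope over a time window
#'
#' Ordinary least-squares slope of dF/F against time across samples in the
#' half-open ramp window (default 3-8 s after cue onset, excluding the cue
#' onset and offset responses). Computed on the unsmoothed dF/F; smoothing
#' in this package is reserved for visualisation.
#'
#' @param trace A [dff_trace()].
#' @param cue_onset_t Cue onset time (s).
#' @param window Window relative to cue onset (s), half-open.
#' @return Slope in percent dF/F per second, or `NA` with a warning when
#'   the window extends past the recording.
#' @export
ramp_slope_time <- function(trace, cue_onset_t, window = c(3, 8)) {
  t <- trace$time_s
  a <- cue_onset_t + window[1]
  b <- cue_onset_t + window[2]
  if (a < t[1] || b > t[length(t)] + (t[2] - t[1])) {
    warning("ramp window outside recording; trial dropped")
    return(NA_real_)
  }
  sel <- .in_window(t, a, b)
  if (sum(sel) < 2) stop("fewer than 2 samples in the ramp window")
  .ols_slope(t[sel], trace$dff_percent[sel])
}

#' Pre-cue dF/F slope
#'
#' OLS slope over the `window_s` seconds preceding cue onset (half-open
#' `[onset - window_s, onset)`), used to check that ramps are not a
#' carry-over of post-reward recovery from the previous trial.
#'
#' @param trace A [dff_trace()].
#' @param cue_onset_t Cue onset time (s).
#' @param window_s Length of the pre-cue window (s), default 2.
#' @return Slope in percent dF/F per second, or `NA` with a warning.
#' @export
pre_cue_slope <- function(trace, cue_onset_t, window_s = 2) {
  t <- trace$time_s
  a <- cue_onset_t - window_s
  if (a < t[1]) {
    warning("pre-cue window outside recording; trial dropped")
    return(NA_real_)
  }
  sel <- .in_window(t, a, cue_onset_t)
  if (sum(sel) < 2) stop("fewer than 2 samples in the pre-cue window")
  .ols_slope(t[sel], trace$dff_percent[sel])
}

#' Gaussian smoothing for visualisation
#'
#' Convolution with a discrete Gaussian kernel (sigma in samples, kernel
#' truncated at 4 sigma, renormalised at the edges). Intended only for
#' plots; all slope and peak quantification in this package operates on
#' the unsmoothed trace.
#'
#' @param x Numeric vector.
#' @param sigma_samples Kernel standard deviation in samples (default 2).
#' @return Smoothed numeric vector of the same length.
#' @export
smooth_gaussian <- function(x, sigma_samples = 2) {
  stopifnot(sigma_samples > 0)
  r <- ceiling(4 * sigma_samples)
  kern <- stats::dnorm(-r:r, sd = sigma_samples)
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - r)
    hi <- min(n, i + r)
    kk <- kern[(lo - i + r + 1):(hi - i + r + 1)]
    out[i] <- sum(x[lo:hi] * kk) / sum(kk)
  }
  out
}

#' Align dF/F samples to virtual-distance samples
#'
#' Distance is sampled every 30 ms while dF/F is sampled every 10 ms, so
#' the average of every three dF/F values is assigned to the corresponding
#' distance sample. Distance samples that do not differ from the previous
#' retained sample's raw predecessor are dropped together with their mean
#' dF/F (this avoids averaging artifacts while the animal is stationary).
#'
#' @param dff_10ms dF/F values on the 10 ms grid.
#' @param distance_30ms Distance samples (cm) on the 30 ms grid.
#' @return Data frame with columns `distance_cm`, `dff_percent`, ordered
#'   as sampled.
#' @export
distance_align <- function(dff_10ms, distance_30ms) {
  n_d <- length(distance_30ms)
  if (abs(length(dff_10ms) - 3 * n_d) > 2) {
    stop("dF/F and distance lengths inconsistent with a 3:1 sample-rate ratio")
  }
  n_full <- min(n_d, length(dff_10ms) %/% 3)
  if (n_full < 1) stop("not enough samples to align")
  dmat <- matrix(dff_10ms[seq_len(3 * n_full)], nrow = 3)
  dff_mean <- colMeans(dmat)
  dist <- distance_30ms[seq_len(n_full)]
  keep <- c(TRUE, diff(dist) != 0)
  data.frame(distance_cm = dist[keep], dff_percent = dff_mean[keep])
}

#' Ramp slope over a virtual-distance window
#'
#' OLS slope of dF/F against distance for aligned pairs in the half-open
#' window (default 20-57 cm of the 67 cm hallway, stopping 10 cm before
#' the end of the track).
#'
#' @param aligned_pairs Data frame from [distance_align()].
#' @param window Distance window (cm), half-open.
#' @return Slope in percent dF/F per cm, or `NA` with a warning when fewer
#'   than 2 pairs fall in the window (the trial is dropped).
#' @export
ramp_slope_distance <- function(aligned_pairs, window = c(20, 57)) {
  sel <- .in_window(aligned_pairs$distance_cm, window[1], window[2])
  if (sum(sel) < 2) {
    warning("fewer than 2 aligned pairs in the distance window; trial dropped")
    return(NA_real_)
  }
  .ols_slope(aligned_pairs$distance_cm[sel], aligned_pairs$dff_percent[sel])
}

#' Per-centimetre binned dF/F
#'
#' Rounds distances to the nearest integer centimetre and averages dF/F
#' within each bin from 0 to `max_cm`; empty bins are `NA`. Used for
#' visualising distance-aligned traces.
#'
#' @param aligned_pairs Data frame from [distance_align()].
#' @param max_cm Largest bin (default 67, the hallway length).
#' @return Data frame with columns `distance_cm` (0..max_cm) and
#'   `dff_percent`.
#' @export
bin_by_cm <- function(aligned_pairs, max_cm = 67) {
  bins <- round(aligned_pairs$distance_cm)
  out <- data.frame(distance_cm = 0:max_cm, dff_percent = NA_real_)
  means <- tapply(aligned_pairs$dff_percent, bins, mean)
  hit <- match(as.numeric(names(means)), out$distance_cm)
  ok <- !is.na(hit)
  out$dff_percent[hit[ok]] <- as.numeric(means)[ok]
  out
}
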