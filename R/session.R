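# Session-level wrappers: raw two-channel session in, trial table out.

#' Assemble a photometry session from raw components
#'
#' @param time_s Sample timestamps (s), regular grid.
#' @param ch470,ch405 Raw fluorescence channels.
#' @param events An [event_stream()].
#' @param lick_times Optional lick times (s).
#' @param distance Optional data frame (`time_s`, `distance_cm`) of
#'   virtual-position samples (VR sessions).
#' @return A list of class `photometry_session`.
#' @export
photometry_session <- function(time_s, ch470, ch405, events,
                               lick_times = NULL, distance = NULL) {
  stopifnot(length(time_s) == length(ch470),
            length(time_s) == length(ch405))
  if (any(diff(time_s) <= 0)) stop("timestamps must be strictly increasing")
  structure(
    list(time_s = time_s, ch470 = ch470, ch405 = ch405, events = events,
         lick_times = lick_times, distance = distance),
    class = "photometry_session"
  )
}

#' Session dF/F trace
#'
#' Runs the isosbestic scaling and dF/F computation for a whole session.
#'
#' @param session A [photometry_session()].
#' @param intercept Affine (default) or scale-only isosbestic fit.
#' @return A [dff_trace()].
#' @export
session_dff <- function(session, intercept = TRUE) {
  fitted <- fit_isosbestic(session$ch405, session$ch470, intercept = intercept)
  dff_trace(session$time_s, compute_dff(session$ch470, fitted))
}

#' Per-trial metrics for a Pavlovian session
#'
#' Computes, for every trial: the ramp slope over the 3-8 s window, the
#' cue-onset peak, the pre-cue slope, the previous ITI
#' (reward to this trial's cue onset) and previous IRI, and - when lick
#' times are present - the anticipatory lick rate and lick slope. Trials
#' whose analysis windows fall outside the recording get `NA` metrics
#' (dropped from downstream fits).
#'
#' @param session A [photometry_session()] whose events use
#'   `cue_onset`/`reward` labels.
#' @param ramp_window Ramp window relative to cue onset (s), half-open.
#' @param pre_cue_window_s Pre-cue slope window length (s).
#' @param intercept Isosbestic fit form (see [fit_isosbestic()]).
#' @param animal_id,condition Optional labels copied into the table.
#' @return A data frame of class `trial_table`, one row per trial.
#' @export
analyze_pavlovian_session <- function(session, ramp_window = c(3, 8),
                                      pre_cue_window_s = 2,
                                      intercept = TRUE,
                                      animal_id = NA_character_,
                                      condition = NA_character_) {
  trace <- session_dff(session, intercept = intercept)
  ev <- session$events
  cues <- ev$time_s[ev$label == "cue_onset"]
  rewards <- ev$time_s[ev$label == "reward"]
  n <- length(cues)
  stopifnot(length(rewards) == n)

  rate <- if (!is.null(session$lick_times)) {
    lick_rate(session$lick_times, t_range = c(0, max(session$time_s)))
  } else NULL

  out <- data.frame(
    trial_index = seq_len(n),
    ramp_slope = NA_real_, onset_peak = NA_real_, pre_cue_slope = NA_real_,
    previous_iti_s = NA_real_, previous_iri_s = NA_real_,
    anticipatory_lick_rate = NA_real_, lick_slope = NA_real_
  )
  tvec <- trace$time_s
  for (i in seq_len(n)) {
    # slice a neighbourhood of the trial once; the window ops then work on
    # a short trace instead of rescanning the whole session
    lo <- findInterval(cues[i] - pre_cue_window_s - 1.5, tvec) + 1
    hi <- findInterval(cues[i] + ramp_window[2] + 1.5, tvec)
    sl <- trace[max(1, lo):hi, ]
    out$ramp_slope[i] <- ramp_slope_time(sl, cues[i], ramp_window)
    out$onset_peak[i] <- onset_peak_response(sl, cues[i])
    out$pre_cue_slope[i] <- pre_cue_slope(sl, cues[i], pre_cue_window_s)
    if (i > 1) {
      out$previous_iti_s[i] <- cues[i] - rewards[i - 1]
      out$previous_iri_s[i] <- rewards[i] - rewards[i - 1]
    }
    if (!is.null(rate)) {
      rlo <- findInterval(cues[i] - 1.5, rate$time_s) + 1
      rhi <- findInterval(cues[i] + 10.5, rate$time_s)
      rsl <- rate[max(1, rlo):rhi, ]
      out$anticipatory_lick_rate[i] <- anticipatory_lick_rate(rsl, cues[i])
      out$lick_slope[i] <- lick_slope(rsl, cues[i], ramp_window)
    }
  }
  out$animal_id <- animal_id
  out$condition <- condition
  class(out) <- c("trial_table", "data.frame")
  out
}

#' Per-trial metrics for a VR session
#'
#' For each trial, dF/F samples between trial onset and reward are aligned
#' to the 30 ms virtual-position samples (three 10 ms dF/F samples per
#' position sample, duplicated positions dropped), and the ramp slope is
#' fit over the 20-57 cm window. The onset peak is computed in time at
#' hallway appearance.
#'
#' @param session A [photometry_session()] with a `distance` component and
#'   `trial_onset`/`reward` event labels.
#' @param window Distance window (cm), half-open.
#' @param intercept Isosbestic fit form.
#' @param animal_id,condition Optional labels.
#' @return A data frame of class `trial_table`, one row per trial, with
#'   `ramp_slope` in percent dF/F per cm and `trial_duration_s`.
#' @export
analyze_vr_session <- function(session, window = c(20, 57),
                               intercept = TRUE,
                               animal_id = NA_character_,
                               condition = NA_character_) {
  if (is.null(session$distance)) stop("session has no distance samples")
  trace <- session_dff(session, intercept = intercept)
  ev <- session$events
  onsets <- ev$time_s[ev$label == "trial_onset"]
  rewards <- ev$time_s[ev$label == "reward"]
  n <- length(onsets)
  dt_dff <- stats::median(diff(trace$time_s))
  dist <- session$distance

  out <- data.frame(
    trial_index = seq_len(n),
    ramp_slope = NA_real_, onset_peak = NA_real_,
    previous_iti_s = NA_real_, previous_iri_s = NA_real_,
    trial_duration_s = rewards - onsets
  )
  for (i in seq_len(n)) {
    dsel <- which(dist$time_s >= onsets[i] & dist$time_s < rewards[i])
    if (length(dsel) < 2) next
    td <- dist$time_s[dsel]
    # the 30 ms window ending at each distance sample spans three 10 ms
    # dF/F samples; map by grid index
    i0 <- round((td[1] - 2 * dt_dff) / dt_dff) + 1
    idx <- i0:(i0 + 3 * length(dsel) - 1)
    if (idx[1] < 1 || idx[length(idx)] > nrow(trace)) next
    pairs <- distance_align(trace$dff_percent[idx], dist$distance_cm[dsel])
    out$ramp_slope[i] <- ramp_slope_distance(pairs, window)
    out$onset_peak[i] <- onset_peak_response(trace, onsets[i])
    if (i > 1) {
      out$previous_iti_s[i] <- onsets[i] - rewards[i - 1]
      out$previous_iri_s[i] <- rewards[i] - rewards[i - 1]
    }
  }
  out$animal_id <- animal_id
  out$condition <- condition
  class(out) <- c("trial_table", "data.frame")
  out
}

#' Write or read a photometry session as CSV files
#'
#' The signal table has columns `time_s`, `ch470`, `ch405`; events are
#' written with [write_event_stream()]. Optional distance samples get
#' their own file with columns `time_s`, `distance_cm`.
#'
#' @param session A [photometry_session()].
#' @param signal_path,events_path,distance_path File paths
#'   (`distance_path` only for VR sessions).
#' @return `read_photometry_session()` returns a [photometry_session()].
#' @export
write_photometry_session <- function(session, signal_path, events_path,
                                     distance_path = NULL) {
  utils::write.csv(data.frame(time_s = session$time_s,
                              ch470 = session$ch470,
                              ch405 = session$ch405),
                   signal_path, row.names = FALSE)
  write_event_stream(session$events, events_path)
  if (!is.null(distance_path) && !is.null(session$distance)) {
    utils::write.csv(session$distance, distance_path, row.names = FALSE)
  }
  invisible(signal_path)
}

#' @rdname write_photometry_session
#' @export
read_photometry_session <- function(signal_path, events_path,
                                    distance_path = NULL) {
  sig <- utils::read.csv(signal_path)
  ev <- read_event_stream(events_path)
  dist <- if (!is.null(distance_path)) utils::read.csv(distance_path) else NULL
  photometry_session(sig$time_s, sig$ch470, sig$ch405, ev, distance = dist)
}
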