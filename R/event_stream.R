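#' Trial configuration for Pavlovian and simulation event streams
#'
#' Encodes the common trial skeleton: an 8 s cue followed by a 1 s trace
#' period before reward. Simulation streams additionally split the cue into
#' `n_subcues` sub-cues at even spacing (a discretisation of the dynamic
#' tone), append the cue offset as its own event, and insert a fixed
#' consummatory period after reward before the ITI clock starts.
#'
#' @param n_trials Number of trials, `>= 1`.
#' @param iti_spec Calibrated [trunc_exp_spec()] for the reward-to-next-cue
#'   interval. For simulation streams its minimum must be at least
#'   `consummatory_s`, since the first `consummatory_s` seconds of the gap
#'   are the consummatory period.
#' @param cue_duration_s Cue length in seconds (default 8).
#' @param trace_s Delay between cue offset and reward (default 1).
#' @param consummatory_s Fixed post-reward consummatory period (simulation
#'   streams only; `NULL` for experimental Pavlovian streams).
#' @param n_subcues Number of sub-cues the simulation splits the cue into
#'   (default 8, i.e. one per second).
#' @param include_offset_event Whether the simulation stream emits the cue
#'   offset as an additional event (default `TRUE`).
#' @return An object of class `trial_config`.
#' @export
trial_config <- function(n_trials, iti_spec,
                         cue_duration_s = 8, trace_s = 1,
                         consummatory_s = NULL,
                         n_subcues = 8, include_offset_event = TRUE) {
  stopifnot(
    n_trials >= 1,
    inherits(iti_spec, "trunc_exp_spec"),
    cue_duration_s >= 0, trace_s >= 0, n_subcues >= 1
  )
  if (!is.null(consummatory_s)) {
    stopifnot(consummatory_s >= 0)
    if (iti_spec$min_s < consummatory_s) {
      stop("iti_spec minimum must be >= consummatory_s for a simulation stream")
    }
  }
  structure(
    list(n_trials = as.integer(n_trials), iti_spec = iti_spec,
         cue_duration_s = cue_duration_s, trace_s = trace_s,
         consummatory_s = consummatory_s, n_subcues = as.integer(n_subcues),
         include_offset_event = isTRUE(include_offset_event)),
    class = "trial_config"
  )
}

#' Construct a labelled event stream
#'
#' An event stream is a data frame of `(time_s, label)` rows with strictly
#' increasing times, measured in seconds from session start.
#'
#' @param time_s Numeric event times (s), strictly increasing.
#' @param label Character event labels.
#' @return A data frame of class `event_stream`.
#' @export
event_stream <- function(time_s, label) {
  stopifnot(length(time_s) == length(label), is.numeric(time_s))
  if (length(time_s) > 1 && any(diff(time_s) <= 0)) {
    stop("event times must be strictly increasing")
  }
  structure(
    data.frame(time_s = as.numeric(time_s), label = as.character(label),
               stringsAsFactors = FALSE),
    class = c("event_stream", "data.frame")
  )
}

#' Build an experimental Pavlovian event stream
#'
#' Each trial is a cue onset followed by reward `cue_duration_s + trace_s`
#' seconds later (9 s under defaults); the next cue onset follows the reward
#' by an ITI draw. There is no consummatory term: for experimental sessions
#' the ITI is defined directly as the reward-to-cue-onset interval.
#'
#' @param config A [trial_config()] (with `consummatory_s = NULL`).
#' @param seed Optional integer seed for the ITI draws.
#' @param itis Optional vector of `n_trials - 1` forced ITIs (s), bypassing
#'   the sampler (useful for deterministic tests).
#' @return An [event_stream()] with labels `cue_onset` and `reward`.
#' @export
build_pavlovian_stream <- function(config, seed = NULL, itis = NULL) {
  stopifnot(inherits(config, "trial_config"))
  n <- config$n_trials
  rr_delay <- config$cue_duration_s + config$trace_s
  if (is.null(itis)) {
    itis <- if (n > 1) sample_itis(config$iti_spec, n - 1, seed = seed) else numeric(0)
  }
  stopifnot(length(itis) == max(n - 1, 0))
  onsets <- cumsum(c(0, rr_delay + itis))
  times <- as.vector(rbind(onsets, onsets + rr_delay))
  labels <- rep(c("cue_onset", "reward"), n)
  out <- event_stream(times, labels)
  attr(out, "itis") <- itis
  attr(out, "config") <- config
  out
}

#' Build a simulation event stream with a sub-cue sequence
#'
#' Each trial emits `cue_1 .. cue_k` at even spacing across the cue period
#' (1 s apart under defaults), the cue offset as an additional event, and
#' reward `trace_s` after offset. The reward-to-next-cue gap is a draw from
#' `config$iti_spec`; its first `consummatory_s` seconds are the fixed
#' consummatory period and the remainder is the simulation ITI. Under the
#' study's settings this yields mean inter-reward intervals of 17 s
#' (short condition) and 64 s (long condition).
#'
#' @inheritParams build_pavlovian_stream
#' @param itis Optional forced reward-to-next-cue gaps (s).
#' @return An [event_stream()] with labels `cue_1..cue_k`, `cue_offset`,
#'   `reward`. The realised consummatory-excluded ITIs are stored in
#'   attribute `sim_itis`.
#' @export
build_simulation_stream <- function(config, seed = NULL, itis = NULL) {
  stopifnot(inherits(config, "trial_config"))
  if (is.null(config$consummatory_s)) {
    stop("simulation streams require consummatory_s in the trial_config")
  }
  n <- config$n_trials
  k <- config$n_subcues
  spacing <- config$cue_duration_s / k
  rr_delay <- config$cue_duration_s + config$trace_s
  if (is.null(itis)) {
    itis <- if (n > 1) sample_itis(config$iti_spec, n - 1, seed = seed) else numeric(0)
  }
  stopifnot(length(itis) == max(n - 1, 0))
  onsets <- cumsum(c(0, rr_delay + itis))

  offs <- (seq_len(k) - 1) * spacing
  labs <- paste0("cue_", seq_len(k))
  if (config$include_offset_event) {
    offs <- c(offs, config$cue_duration_s)
    labs <- c(labs, "cue_offset")
  }
  offs <- c(offs, rr_delay)
  labs <- c(labs, "reward")

  times <- as.vector(vapply(onsets, function(t0) t0 + offs, numeric(length(offs))))
  labels <- rep(labs, n)
  out <- event_stream(times, labels)
  attr(out, "itis") <- itis
  attr(out, "sim_itis") <- itis - config$consummatory_s
  attr(out, "config") <- config
  out
}

#' Inter-reward intervals of an event stream
#'
#' @param stream An [event_stream()] containing `reward` events.
#' @return Numeric vector of intervals between consecutive rewards (s).
#' @export
inter_reward_intervals <- function(stream) {
  diff(stream$time_s[stream$label == "reward"])
}

#' Reward-to-next-cue-onset intervals (experimental ITI definition)
#'
#' @param stream An [event_stream()].
#' @return Numeric vector: for each trial after the first, the time from the
#'   previous reward to that trial's first cue event.
#' @export
inter_trial_intervals <- function(stream) {
  first_lab <- stream$label[1]
  onsets <- stream$time_s[stream$label == first_lab]
  rewards <- stream$time_s[stream$label == "reward"]
  n <- min(length(onsets) - 1, length(rewards))
  onsets[1 + seq_len(n)] - rewards[seq_len(n)]
}

#' Auditory tone frequency at a time within the cue
#'
#' Dynamic tones step by 0.08 kHz every 0.2 s across the 8 s cue (3.2 kHz
#' total change): `dynamic_up` starts at 3 kHz and rises, `dynamic_down`
#' starts at 12 kHz and falls. `fixed_12` plays 12 kHz continuously;
#' `fixed_3` is pulsed 200 ms on / 200 ms off and returns `NA` during the
#' silent half-cycles.
#'
#' @param tone_kind One of `"dynamic_up"`, `"dynamic_down"`, `"fixed_3"`,
#'   `"fixed_12"`.
#' @param t_s Time(s) since cue onset, each in `[0, 8]` seconds.
#' @param start_khz Optional starting frequency override (kHz); defaults to
#'   3 (up, fixed_3) or 12 (down, fixed_12).
#' @return Frequency in kHz (vectorised over `t_s`); `NA` denotes silence.
#' @export
tone_frequency_profile <- function(tone_kind = c("dynamic_up", "dynamic_down",
                                                 "fixed_3", "fixed_12"),
                                   t_s, start_khz = NULL) {
  tone_kind <- match.arg(tone_kind)
  if (any(t_s < 0 | t_s > 8)) stop("t_s outside the 8 s cue period")
  step <- floor(t_s / 0.2 + 1e-9)
  if (is.null(start_khz)) {
    start_khz <- switch(tone_kind, dynamic_up = 3, dynamic_down = 12,
                        fixed_3 = 3, fixed_12 = 12)
  }
  switch(tone_kind,
    dynamic_up   = start_khz + 0.08 * step,
    dynamic_down = start_khz - 0.08 * step,
    fixed_12     = rep(start_khz, length(t_s)),
    fixed_3      = ifelse(step %% 2 == 0, start_khz, NA_real_)
  )
}

#' Write or read an event stream as CSV
#'
#' @param stream An [event_stream()].
#' @param path File path.
#' @return `read_event_stream()` returns an [event_stream()];
#'   `write_event_stream()` returns `path` invisibly.
#' @export
write_event_stream <- function(stream, path) {
  utils::write.csv(as.data.frame(stream)[, c("time_s", "label")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_stream
#' @export
read_event_stream <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  event_stream(df$time_s, df$label)
}
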