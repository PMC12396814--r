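#' Ground truth for a synthetic session
#'
#' Every parameter the synthetic generators use, so that pipeline estimates
#' can be checked against known truths. Condition presets encode the
#' qualitative regimes of the task designs: long-ITI conditions have a
#' large cue-onset transient and no ramp; the short-ITI dynamic condition
#' has a small onset transient and a positive within-cue ramp whose
#' per-trial slope depends negatively on the previous ITI; fixed-tone
#' conditions have no ramp. Session sizes mirror the task designs
#' (100 trials short-ITI, 40 long-ITI Pavlovian, 50 VR).
#'
#' @param condition One of `"SD"`, `"LD"`, `"SF"`, `"LF"`, `"VR-short"`,
#'   `"VR-long"`.
#' @param n_trials Trials per session (condition default if `NULL`).
#' @param seed Integer seed stored with the truth and used by the
#'   generators.
#' @param ... Overrides for any preset field (e.g. `noise_sd`,
#'   `beta_iti`, `ramp_slope_base`, `dip_amplitude`, `bleach`).
#' @return An object of class `ground_truth`.
#' @section Fields:
#' `onset_amplitude`, `reward_amplitude` (percent dF/F); `ramp_slope_base`
#' (percent dF/F per s, or per cm for VR) and `beta_iti` (change in slope
#' per second of previous ITI); `slope_noise_sd` (trial-to-trial slope
#' scatter); `dip_amplitude` (`<= 0`) and `dip_recovery_tau_s` for the
#' post-reward undershoot; `bleach` (double-exponential amplitudes and
#' time constants for the 405 channel and for 470-specific drift the
#' isosbestic cannot capture); `noise_sd` per channel (raw units);
#' `lick_baseline_hz`, `lick_peak_hz`; `velocity_plateau_cm_s`,
#' `velocity_rise_tau_s`, `iti_belt_speed_cm_s`; `hallway_cm` (67).
#' @export
ground_truth <- function(condition = c("SD", "LD", "SF", "LF",
                                       "VR-short", "VR-long"),
                         n_trials = NULL, seed = 1L, ...) {
  condition <- match.arg(condition)
  preset <- switch(condition,
    "SD" = list(iti_spec = iti_spec_preset("short"), n_trials = 100L,
                onset_amplitude = 1.5, ramp_slope_base = 0.6,
                beta_iti = -0.045, slope_noise_sd = 0.15),
    "SF" = list(iti_spec = iti_spec_preset("short"), n_trials = 100L,
                onset_amplitude = 1.5, ramp_slope_base = 0,
                beta_iti = 0, slope_noise_sd = 0.15),
    "LD" = list(iti_spec = iti_spec_preset("long"), n_trials = 40L,
                onset_amplitude = 4, ramp_slope_base = 0,
                beta_iti = 0, slope_noise_sd = 0.15),
    "LF" = list(iti_spec = iti_spec_preset("long"), n_trials = 40L,
                onset_amplitude = 4, ramp_slope_base = 0,
                beta_iti = 0, slope_noise_sd = 0.15),
    "VR-short" = list(iti_spec = iti_spec_preset("vr_short"), n_trials = 50L,
                      onset_amplitude = 1.5, ramp_slope_base = 0.08,
                      beta_iti = 0, slope_noise_sd = 0.02),
    "VR-long" = list(iti_spec = iti_spec_preset("vr_long"), n_trials = 50L,
                     onset_amplitude = 4, ramp_slope_base = 0,
                     beta_iti = 0, slope_noise_sd = 0.02)
  )
  gt <- c(preset, list(
    condition = condition,
    reward_amplitude = 3,
    dip_amplitude = -1.5,
    dip_recovery_tau_s = 3,
    bleach = list(
      ch405 = list(amps = c(0.20, 0.08), taus = c(300, 1800)),
      ch470_extra = list(amps = c(0.02, 0.01), taus = c(240, 1500))
    ),
    noise_sd = c(ch470 = 0.003, ch405 = 0.003),
    f405_base = 0.8, gain_a = 1.5, offset_c = 0.1,
    lick_baseline_hz = 2, lick_peak_hz = 6,
    velocity_plateau_cm_s = 20, velocity_rise_tau_s = 0.5,
    iti_belt_speed_cm_s = 2,
    hallway_cm = 67,
    cue_duration_s = 8, trace_s = 1,
    pad_start_s = 5, sample_rate_hz = 120,
    seed = as.integer(seed)
  ))
  dots <- list(...)
  for (nm in names(dots)) gt[[nm]] <- dots[[nm]]
  if (!is.null(n_trials)) gt$n_trials <- as.integer(n_trials)
  if (any(gt$noise_sd < 0)) stop("noise_sd must be nonnegative")
  if (gt$dip_amplitude > 0) stop("dip_amplitude must be <= 0")
  structure(gt, class = "ground_truth")
}

# Double-exponential bleaching multiplier (relative to asymptote 1).
.bleach_curve <- function(t, comp) {
  1 + comp$amps[1] * exp(-t / comp$taus[1]) +
      comp$amps[2] * exp(-t / comp$taus[2])
}

# Additive slow drift (relative units, decaying to 0).
.drift_curve <- function(t, comp) {
  comp$amps[1] * exp(-t / comp$taus[1]) + comp$amps[2] * exp(-t / comp$taus[2])
}

# Per-trial injected ramp slopes. The first trial has no previous ITI; its
# slope uses the sampler's target mean so every trial has a defined truth.
.true_slopes <- function(gt, prev_iti) {
  prev <- ifelse(is.na(prev_iti), gt$iti_spec$target_mean_s, prev_iti)
  gt$ramp_slope_base + gt$beta_iti * prev +
    stats::rnorm(length(prev), 0, gt$slope_noise_sd)
}

# Add the dopamine kernels of one Pavlovian trial to the percent-dF/F
# vector D defined on the regular time grid with step h. All windows are
# half-open; indices are computed arithmetically so cost is O(window),
# not O(session).
.add_pav_trial_kernels <- function(D, h, cue_t, reward_t, slope, gt) {
  n <- length(D)
  tval <- function(idx) (idx - 1) * h
  # cue-onset transient
  idx <- .grid_window_idx(n, h, cue_t, cue_t + 2.5)
  D[idx] <- D[idx] + gt$onset_amplitude * exp(-(tval(idx) - cue_t) / 0.6)
  # linear within-cue ramp, anchored at zero 3 s after onset
  idx <- .grid_window_idx(n, h, cue_t + 2.5, cue_t + 8.5)
  D[idx] <- D[idx] + slope * (tval(idx) - cue_t - 3)
  idx <- .grid_window_idx(n, h, cue_t + 8.5, cue_t + 10)
  D[idx] <- D[idx] + slope * 5.5 * exp(-(tval(idx) - cue_t - 8.5) / 0.3)
  # reward transient and post-reward dip with exponential recovery
  idx <- .grid_window_idx(n, h, reward_t, reward_t + 3)
  D[idx] <- D[idx] + gt$reward_amplitude * exp(-(tval(idx) - reward_t) / 0.7)
  idx <- .grid_window_idx(n, h, reward_t, reward_t + 12 * gt$dip_recovery_tau_s)
  dlt <- tval(idx) - reward_t
  D[idx] <- D[idx] + gt$dip_amplitude * (1 - exp(-dlt / 0.5)) *
    exp(-dlt / gt$dip_recovery_tau_s)
  D
}

# Compose the two raw channels from a clean 405 baseline and the percent
# dopamine signal D, then add channel noise.
.compose_channels <- function(tg, D, gt) {
  b405 <- gt$f405_base * .bleach_curve(tg, gt$bleach$ch405)
  g <- gt$gain_a * b405 + gt$offset_c
  ch405 <- b405 + stats::rnorm(length(tg), 0, gt$noise_sd["ch405"])
  ch470 <- g * (1 + D / 100) + .drift_curve(tg, gt$bleach$ch470_extra) +
    stats::rnorm(length(tg), 0, gt$noise_sd["ch470"])
  list(ch405 = ch405, ch470 = ch470)
}

#' Generate a synthetic Pavlovian photometry session
#'
#' Builds a Pavlovian event stream from the ground truth's ITI
#' specification, then synthesises two raw fluorescence channels on a
#' 120 Hz grid: the 405 channel is a double-exponential bleaching baseline
#' plus noise; the 470 channel is an affine function of the clean 405
#' baseline, modulated multiplicatively by the percent dopamine signal
#' (cue-onset transient, within-cue linear ramp over 3-8 s with slope
#' `ramp_slope_base + beta_iti * previous_iti` plus trial scatter, reward
#' transient, post-reward dip), plus 470-specific drift and noise. A lick
#' train is attached. All generating values are recorded for recovery
#' testing.
#'
#' @param gt A [ground_truth()] for a Pavlovian condition.
#' @param licks Attach a lick train (default `TRUE`); disable when only
#'   the photometry channels are needed, e.g. in large recovery studies.
#' @return A list of class `c("synthetic_session", "photometry_session")`:
#'   `time_s`, `ch470`, `ch405`, `events` (an [event_stream()]),
#'   `lick_times`, `ground_truth`, `clean_dff` (the injected percent
#'   dopamine signal before channel composition, for exact-construction
#'   checks), and `truths` (per-trial `previous_iti_s` and injected
#'   `ramp_slope`).
#' @export
generate_photometry_session <- function(gt, licks = TRUE) {
  stopifnot(inherits(gt, "ground_truth"))
  if (startsWith(gt$condition, "VR")) stop("use generate_vr_session() for VR conditions")
  set.seed(gt$seed)
  cfg <- trial_config(gt$n_trials, gt$iti_spec,
                      cue_duration_s = gt$cue_duration_s, trace_s = gt$trace_s)
  stream <- build_pavlovian_stream(cfg)
  stream$time_s <- stream$time_s + gt$pad_start_s
  itis <- attr(stream, "itis")
  prev_iti <- c(NA_real_, itis)
  slopes <- .true_slopes(gt, prev_iti)

  cues <- stream$time_s[stream$label == "cue_onset"]
  rewards <- stream$time_s[stream$label == "reward"]
  t_end <- rewards[length(rewards)] + 10
  tg <- seq(0, t_end, by = 1 / gt$sample_rate_hz)

  D <- numeric(length(tg))
  for (i in seq_len(gt$n_trials)) {
    D <- .add_pav_trial_kernels(D, 1 / gt$sample_rate_hz, cues[i],
                                rewards[i], slopes[i], gt)
  }
  ch <- .compose_channels(tg, D, gt)
  lick_times <- if (licks) generate_lick_train(gt, stream) else NULL

  structure(
    list(time_s = tg, ch470 = ch$ch470, ch405 = ch$ch405,
         events = stream, lick_times = lick_times, distance = NULL,
         ground_truth = gt, clean_dff = D,
         truths = data.frame(trial_index = seq_len(gt$n_trials),
                             previous_iti_s = prev_iti,
                             ramp_slope = slopes)),
    class = c("synthetic_session", "photometry_session")
  )
}

#' Generate an inhomogeneous-Poisson lick train
#'
#' Baseline rate everywhere; during each cue the rate ramps linearly from
#' baseline up to the peak rate, holds the peak through the 1 s trace
#' period, and returns to baseline at reward. Licks are drawn per 10 ms
#' bin from the local rate and jittered uniformly within the bin.
#'
#' @param gt A [ground_truth()].
#' @param events An [event_stream()] with `cue_onset`/`trial_onset` and
#'   `reward` labels.
#' @return Sorted numeric vector of lick times (s).
#' @export
generate_lick_train <- function(gt, events) {
  onset_lab <- if ("cue_onset" %in% events$label) "cue_onset" else "trial_onset"
  cues <- events$time_s[events$label == onset_lab]
  rewards <- events$time_s[events$label == "reward"]
  t_end <- max(events$time_s) + 10
  bin <- 0.01
  tg <- seq(0, t_end - bin, by = bin)
  rate <- rep(gt$lick_baseline_hz, length(tg))
  dur <- gt$cue_duration_s
  n <- length(tg)
  for (i in seq_along(cues)) {
    idx <- .grid_window_idx(n, bin, cues[i], cues[i] + dur)
    rate[idx] <- gt$lick_baseline_hz +
      (gt$lick_peak_hz - gt$lick_baseline_hz) * (tg[idx] - cues[i]) / dur
    idx <- .grid_window_idx(n, bin, cues[i] + dur, cues[i] + dur + gt$trace_s)
    rate[idx] <- gt$lick_peak_hz
  }
  counts <- stats::rpois(length(tg), rate * bin)
  idx <- rep(seq_along(tg), counts)
  sort(tg[idx] + stats::runif(length(idx), 0, bin))
}

#' Generate a synthetic virtual-reality session
#'
#' Each trial the virtual position rises from 0 to 67 cm following a
#' smooth velocity profile (exponential rise to a plateau); reward is
#' delivered on reaching the end of the hallway, and the screen stays
#' blank (position 0) through a truncated-exponential ITI. dF/F is
#' synthesised on a 10 ms grid with an onset transient at hallway
#' appearance, a linear ramp in distance over 20-57 cm with per-trial
#' slope (`ramp_slope_base + beta_iti * previous_iti` plus scatter),
#' reward transient and post-reward dip. Virtual position is sampled
#' every 30 ms and cumulative belt distance every 50 ms.
#'
#' @param gt A [ground_truth()] for a VR condition.
#' @return A `synthetic_session` with `distance` (30 ms virtual position)
#'   and `belt_distance` (50 ms cumulative belt distance) components.
#' @export
generate_vr_session <- function(gt) {
  stopifnot(inherits(gt, "ground_truth"))
  if (!startsWith(gt$condition, "VR")) stop("use generate_photometry_session() for Pavlovian conditions")
  set.seed(gt$seed)
  v <- gt$velocity_plateau_cm_s
  tau <- gt$velocity_rise_tau_s
  pos_at <- function(u) v * (u - tau * (1 - exp(-u / tau)))
  t_end_trial <- stats::uniroot(function(u) pos_at(u) - gt$hallway_cm,
                                lower = 1e-6, upper = 1e3)$root

  n <- gt$n_trials
  itis <- sample_itis(gt$iti_spec, n)
  onsets <- numeric(n)
  onsets[1] <- gt$pad_start_s
  for (i in seq_len(n - 1)) {
    onsets[i + 1] <- onsets[i] + t_end_trial + itis[i]
  }
  rewards <- onsets + t_end_trial
  prev_iti <- c(NA_real_, itis[seq_len(n - 1)])
  slopes <- .true_slopes(gt, prev_iti)

  t_end <- rewards[n] + 10
  tg <- seq(0, t_end, by = 0.01)
  pos_t <- function(t) { # virtual position at session time t
    p <- numeric(length(t))
    for (i in seq_len(n)) {
      sel <- t >= onsets[i] & t < rewards[i]
      p[sel] <- pmin(pos_at(t[sel] - onsets[i]), gt$hallway_cm)
    }
    p
  }

  D <- numeric(length(tg))
  pos_fine <- pos_t(tg)
  for (i in seq_len(n)) {
    sel <- .in_window(tg, onsets[i], onsets[i] + 2.5)
    D[sel] <- D[sel] + gt$onset_amplitude * exp(-(tg[sel] - onsets[i]) / 0.6)
    intrial <- tg >= onsets[i] & tg < rewards[i]
    ramp_sel <- intrial & pos_fine >= 20
    D[ramp_sel] <- D[ramp_sel] + slopes[i] * (pmin(pos_fine[ramp_sel], 57) - 20)
    sel <- .in_window(tg, rewards[i], rewards[i] + 3)
    D[sel] <- D[sel] + gt$reward_amplitude * exp(-(tg[sel] - rewards[i]) / 0.7)
    sel <- .in_window(tg, rewards[i], rewards[i] + 12 * gt$dip_recovery_tau_s)
    dlt <- tg[sel] - rewards[i]
    D[sel] <- D[sel] + gt$dip_amplitude * (1 - exp(-dlt / 0.5)) *
      exp(-dlt / gt$dip_recovery_tau_s)
  }
  ch <- .compose_channels(tg, D, gt)

  t30 <- seq(0, t_end, by = 0.03)
  distance <- data.frame(time_s = t30, distance_cm = pos_t(t30))

  t50 <- seq(0, t_end, by = 0.05)
  belt_v <- rep(gt$iti_belt_speed_cm_s, length(t50))
  for (i in seq_len(n)) {
    sel <- t50 >= onsets[i] & t50 < rewards[i]
    belt_v[sel] <- v * (1 - exp(-(t50[sel] - onsets[i]) / tau))
  }
  belt <- data.frame(time_s = t50, distance_cm = cumsum(belt_v * 0.05))

  ev <- event_stream(as.vector(rbind(onsets, rewards)),
                     rep(c("trial_onset", "reward"), n))
  licks <- generate_lick_train(gt, ev)

  structure(
    list(time_s = tg, ch470 = ch$ch470, ch405 = ch$ch405,
         events = ev, lick_times = licks,
         distance = distance, belt_distance = belt,
         ground_truth = gt, clean_dff = D,
         truths = data.frame(trial_index = seq_len(n),
                             previous_iti_s = prev_iti,
                             ramp_slope = slopes,
                             trial_duration_s = t_end_trial)),
    class = c("synthetic_session", "photometry_session")
  )
}

#' Ground-truth manifest of a synthetic session
#'
#' Collects every generating parameter and per-trial truth of a synthetic
#' session into a serialisable record, for recovery assertions and
#' reproducibility (the stored seed regenerates the session exactly).
#'
#' @param session A session from [generate_photometry_session()] or
#'   [generate_vr_session()].
#' @return A list of class `gt_manifest`.
#' @export
ground_truth_manifest <- function(session) {
  if (!inherits(session, "synthetic_session") || is.null(session$ground_truth)) {
    stop("not a synthetic session: no ground truth available")
  }
  gt <- session$ground_truth
  gt$iti_spec <- unclass(gt$iti_spec)
  structure(
    list(ground_truth = unclass(gt),
         truths = session$truths),
    class = "gt_manifest"
  )
}

#' Write or read a ground-truth manifest (JSON with a checksum)
#'
#' The manifest is serialised as JSON with an embedded checksum of its
#' payload; [read_manifest()] recomputes the checksum and raises an error
#' if the file has been altered.
#'
#' @param manifest A `gt_manifest` from [ground_truth_manifest()].
#' @param path File path.
#' @return `read_manifest()` returns the manifest list;
#'   `write_manifest()` returns `path` invisibly.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "gt_manifest"))
  payload <- jsonlite::toJSON(unclass(manifest), auto_unbox = TRUE,
                              digits = 12, null = "null")
  obj <- list(payload = as.character(payload),
              checksum = .text_checksum(as.character(payload)))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE), path)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  obj <- jsonlite::fromJSON(paste(readLines(path, warn = FALSE),
                                  collapse = "\n"))
  if (!identical(.text_checksum(obj$payload), obj$checksum)) {
    stop("manifest checksum mismatch: file corrupted or tampered with")
  }
  out <- jsonlite::fromJSON(obj$payload)
  class(out) <- "gt_manifest"
  out
}
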