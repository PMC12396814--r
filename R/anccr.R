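#' ANCCR model parameters
#'
#' Constants of the retrospective causal-learning (ANCCR) simulator. The
#' defaults are the published simulation settings: contingency weight
#' `w = 0.5`, innate values `b_cues = 0` and `b_reward = 0.5`,
#' meaningfulness `threshold = 0.2`, eligibility time constant
#' `T = k * IRI` with `k = 0.2`, baseline learning rate `alpha0 = 5e-3`
#' on a `dt = 0.2` s sampling grid, value learning rate `alphaR = 1`,
#' 20 iterations of 1000 trials with the last 100 analysed.
#'
#' @param alpha0 Baseline learning rate, in (0, 1).
#' @param alphaR Value learning rate, in (0, 1].
#' @param w Weight of the prospective (base-rate-corrected) contingency in
#'   the net contingency, in \[0, 1\].
#' @param b_cues,b_reward Innate value per event type.
#' @param threshold Meaningfulness cutoff on estimated value.
#' @param k Eligibility time-constant multiplier, `T = k * IRI`.
#' @param dt Baseline sampling step (s).
#' @param n_iterations,n_trials,n_analysis_trials Simulation sizes.
#' @param online_iri If `TRUE`, track the inter-reward interval with a
#'   running mean and update `T` and the event learning rate as it evolves;
#'   by default both are fixed from the condition's mean IRI, matching the
#'   published simulations (trial-by-trial time-constant changes were not
#'   modelled there).
#' @param add_innate_to_reward If `TRUE` (default) the reward's innate value
#'   is added to its dopamine output; cues' innate values only seed their
#'   value estimates.
#' @return An object of class `anccr_params`.
#' @export
anccr_params <- function(alpha0 = 5e-3, alphaR = 1, w = 0.5,
                         b_cues = 0, b_reward = 0.5, threshold = 0.2,
                         k = 0.2, dt = 0.2,
                         n_iterations = 20L, n_trials = 1000L,
                         n_analysis_trials = 100L,
                         online_iri = FALSE,
                         add_innate_to_reward = TRUE) {
  stopifnot(
    alpha0 > 0, alpha0 < 1, alphaR > 0, alphaR <= 1,
    w >= 0, w <= 1, dt > 0, k > 0, threshold >= 0,
    n_trials >= n_analysis_trials
  )
  structure(
    list(alpha0 = alpha0, alphaR = alphaR, w = w, b_cues = b_cues,
         b_reward = b_reward, threshold = threshold, k = k, dt = dt,
         n_iterations = as.integer(n_iterations),
         n_trials = as.integer(n_trials),
         n_analysis_trials = as.integer(n_analysis_trials),
         online_iri = isTRUE(online_iri),
         add_innate_to_reward = isTRUE(add_innate_to_reward)),
    class = "anccr_params"
  )
}

#' Eligibility trace of an event type
#'
#' The eligibility trace at time `query_t` is the sum over all past
#' occurrences `t_i <= query_t` of `exp(-(query_t - t_i) / time_constant)`:
#' an exponentially decaying memory of how recently and how often the event
#' has occurred. This direct summation is the reference form; the simulator
#' maintains the same quantity with an O(1) recursion (decay between
#' events, then increment by 1 at each occurrence), and the two agree to
#' numerical precision.
#'
#' @param event_times Occurrence times (s) of the event, all `<= query_t`.
#' @param time_constant Decay time constant `T > 0` (s).
#' @param query_t Query time (s).
#' @return Eligibility value (dimensionless, `>= 0`).
#' @export
eligibility_trace <- function(event_times, time_constant, query_t) {
  if (time_constant <= 0) stop("time_constant must be positive")
  if (any(event_times > query_t)) stop("event_times must not exceed query_t")
  if (length(event_times) == 0) return(0)
  sum(exp(-(query_t - event_times) / time_constant))
}

#' Recursive form of the eligibility trace
#'
#' Sequentially decays then increments across occurrences, returning the
#' trace at `query_t`. Used to verify the simulator's O(1) update against
#' the direct summation of [eligibility_trace()].
#'
#' @inheritParams eligibility_trace
#' @export
eligibility_trace_recursive <- function(event_times, time_constant, query_t) {
  if (time_constant <= 0) stop("time_constant must be positive")
  if (any(event_times > query_t)) stop("event_times must not exceed query_t")
  e <- 0
  t_prev <- -Inf
  for (t in sort(event_times)) {
    e <- if (is.finite(t_prev)) e * exp(-(t - t_prev) / time_constant) else 0
    e <- e + 1
    t_prev <- t
  }
  if (is.finite(t_prev)) e * exp(-(query_t - t_prev) / time_constant) else 0
}

#' Update a pairwise event memory
#'
#' Memory of a predecessor sampled at occurrences of a target event moves a
#' fraction `alpha` toward the predecessor's eligibility at that moment:
#' `M' = M + alpha * (E - M)`, a convex combination.
#'
#' @param M Current memory value.
#' @param E_at_event Eligibility of the predecessor at the event.
#' @param alpha Learning rate in (0, 1].
#' @export
update_event_memory <- function(M, E_at_event, alpha) {
  if (!(alpha > 0 && alpha <= 1)) stop("alpha must lie in (0, 1]")
  M + alpha * (E_at_event - M)
}

#' Update a baseline memory sample
#'
#' The baseline memory of an event type is the same convex update with rate
#' `alpha0`, applied on a fixed `dt` grid rather than at events, so it
#' tracks the long-run time-average of the eligibility trace.
#'
#' @param Mbar Current baseline memory.
#' @param E_at_sample Eligibility at the grid sample.
#' @param alpha0 Baseline learning rate in (0, 1].
#' @export
update_baseline_memory <- function(Mbar, E_at_sample, alpha0) {
  update_event_memory(Mbar, E_at_sample, alpha0)
}

#' Predecessor representation contingency
#'
#' The retrospective association strength: the memory of a predecessor
#' sampled at the target minus that predecessor's baseline memory,
#' `PRC = M - Mbar`.
#'
#' @param M Event-sampled memory.
#' @param Mbar Baseline memory.
#' @export
predecessor_contingency <- function(M, Mbar) {
  M - Mbar
}

#' Adaptive event learning rate
#'
#' During initial learning the per-event learning rate compounds the
#' baseline rate over one inter-reward interval of baseline samples:
#' `alpha = 1 - (1 - alpha0)^(IRI / dt)`. It equals `alpha0` at
#' `IRI = dt` and increases monotonically toward 1 with the IRI.
#'
#' @param IRI Inter-reward interval (s), positive.
#' @param alpha0 Baseline learning rate in (0, 1).
#' @param dt Baseline sampling step (s).
#' @export
adaptive_alpha <- function(IRI, alpha0, dt = 0.2) {
  if (any(IRI <= 0)) stop("IRI must be positive")
  stopifnot(alpha0 > 0, alpha0 < 1, dt > 0)
  1 - (1 - alpha0)^(IRI / dt)
}

#' Eligibility time constant from the inter-reward interval
#'
#' `T = k * IRI`: memory maintenance scales with the environment's reward
#' timescale, so frequent rewards (short IRI) give a short memory.
#'
#' @param IRI Inter-reward interval (s), positive.
#' @param k Positive multiplier (0.2 in the published simulations).
#' @export
eligibility_time_constant <- function(IRI, k = 0.2) {
  if (any(IRI <= 0)) stop("IRI must be positive")
  if (any(k <= 0)) stop("k must be positive")
  k * IRI
}

# Closed-form baseline update across a gap of n grid samples during which
# the eligibility decays geometrically (ratio rho per step) from E1 at the
# first sample:
#   Mbar' = (1-a0)^n Mbar + a0 * E1 * sum_{m=0}^{n-1} (1-a0)^{n-1-m} rho^m
# The sum is ((1-a0)^n - rho^n) / ((1-a0) - rho). Equivalent to stepping
# update_baseline_memory() n times (see the property tests).
.baseline_gap_update <- function(Mbar, E1, n, alpha0, rho) {
  if (n <= 0) return(Mbar)
  aa <- 1 - alpha0
  s <- if (abs(aa - rho) < 1e-12) n * aa^(n - 1) else (aa^n - rho^n) / (aa - rho)
  aa^n * Mbar + alpha0 * E1 * s
}

#' Run the ANCCR engine over one event stream
#'
#' Event-driven pass: eligibility traces decay continuously; baseline
#' memories update on the global `dt` grid (via an exact closed form across
#' inter-event gaps); at each occurrence of a meaningful event, pairwise
#' memories update with the adaptive learning rate, causal credit is
#' assigned to predecessors, and the event's estimated value is refreshed.
#' The dopamine response at each event is composed from its stored adjusted
#' net contingencies toward meaningful targets.
#'
#' @param stream An [event_stream()].
#' @param params An [anccr_params()].
#' @param iri_mean Mean inter-reward interval (s) used to fix the
#'   eligibility time constant and learning rate; defaults to the stream's
#'   realised mean IRI.
#' @return A list of class `anccr_run`: `events` (data frame with
#'   `time_s`, `label`, `trial`, `dopamine`) and `state` (final model
#'   state: labels, `E`, `M`, `Mbar`, `ANCCR`, `R`, `meaningful`,
#'   `time_constant`, `alpha`).
#' @export
run_anccr <- function(stream, params = anccr_params(), iri_mean = NULL) {
  stopifnot(inherits(stream, "data.frame"), inherits(params, "anccr_params"))
  labels <- unique(stream$label)
  K <- length(labels)
  idx <- match(stream$label, labels)
  times <- stream$time_s
  reward_k <- match("reward", labels)
  if (is.na(reward_k)) stop("stream must contain reward events")
  reward_times <- times[stream$label == "reward"]
  if (is.null(iri_mean)) {
    if (length(reward_times) < 2) stop("need >= 2 rewards to estimate the IRI")
    iri_mean <- mean(diff(reward_times))
  }
  dt <- params$dt
  tc <- eligibility_time_constant(iri_mean, params$k)
  alpha <- adaptive_alpha(iri_mean, params$alpha0, dt)
  a0 <- params$alpha0
  rho <- exp(-dt / tc)

  b <- ifelse(labels == "reward", params$b_reward, params$b_cues)
  E <- numeric(K)
  M <- matrix(0, K, K, dimnames = list(labels, labels))     # M[k, j]: memory of k at j
  Mbar <- numeric(K)
  ANCCR <- matrix(0, K, K, dimnames = list(labels, labels)) # credit of k toward target j
  R <- b
  meaningful <- R > params$threshold
  last_t <- rep(-Inf, K)
  iri_run <- iri_mean
  n_iri <- 0L
  last_reward_t <- NA_real_

  da <- numeric(length(times))
  t_prev <- 0
  grid_prev <- 0L
  all_k <- seq_len(K)

  for (e in seq_along(times)) {
    t <- times[e]
    j <- idx[e]

    # baseline samples on the dt grid in (t_prev, t]
    n_new <- floor(t / dt + 1e-9) - grid_prev
    if (n_new > 0) {
      g1 <- (grid_prev + 1) * dt
      E1 <- E * exp(-(g1 - t_prev) / tc)
      Mbar <- .baseline_gap_update(Mbar, E1, n_new, a0, rho)
      grid_prev <- grid_prev + n_new
    }

    # eligibility decay to the event, then increment for the occurring type
    E <- E * exp(-(t - t_prev) / tc)
    prev_occ_j <- last_t[j]
    E[j] <- E[j] + 1

    M[, j] <- M[, j] + alpha * (E - M[, j])
    if (meaningful[j]) {
      ANCCR[, j] <- .anccr_credits(M, Mbar, R, last_t, prev_occ_j, j, params)
    }

    da[e] <- .compose_dopamine(ANCCR, meaningful, b, j, reward_k, params)

    cross <- meaningful & all_k != j
    R[j] <- R[j] + params$alphaR * (b[j] + sum(ANCCR[j, cross]) - R[j])
    if (!meaningful[j] && R[j] > params$threshold) meaningful[j] <- TRUE
    last_t[j] <- t

    if (params$online_iri && j == reward_k) {
      if (!is.na(last_reward_t)) {
        n_iri <- n_iri + 1L
        iri_run <- iri_run + (t - last_reward_t - iri_run) / n_iri
        tc <- eligibility_time_constant(iri_run, params$k)
        alpha <- adaptive_alpha(iri_run, params$alpha0, dt)
        rho <- exp(-dt / tc)
      }
      last_reward_t <- t
    }

    t_prev <- t
  }

  first_lab <- stream$label[1]
  trial <- cumsum(stream$label == first_lab)
  state <- list(labels = labels, E = E, M = M, Mbar = Mbar, ANCCR = ANCCR,
                R = R, meaningful = meaningful, b = b,
                time_constant = tc, alpha = alpha, iri_mean = iri_mean)
  structure(
    list(events = data.frame(time_s = times, label = stream$label,
                             trial = trial, dopamine = da,
                             stringsAsFactors = FALSE),
         state = state),
    class = "anccr_run"
  )
}

# Net contingency of each row event on a target column event:
# PRC = M[k, target] - Mbar[k]; the prospective contingency applies a
# Bayes base-rate correction, SRC = PRC * Mbar[target] / Mbar[k]; the net
# contingency mixes the two, NC = w * SRC + (1 - w) * PRC.
.net_contingency <- function(M, Mbar, target, rows, w) {
  prc <- M[rows, target] - Mbar[rows]
  ratio <- ifelse(Mbar[rows] > 1e-12,
                  max(Mbar[target], 0) / pmax(Mbar[rows], 1e-12), 1)
  w * (prc * ratio) + (1 - w) * prc
}

# Adjusted net contingencies of every predecessor type toward target j,
# computed at an occurrence of j (retrospective credit assignment).
#
# Each predecessor's raw contribution is NC * R[j]. Predecessors then
# compete for credit in order of occurrence: an event's contribution is
# adjusted downward by the credit already assigned to events that predict
# its own occurrence (each earlier event m discounts k by m's positive
# net contingency on k times m's credit). With a long eligibility time
# constant this concentrates credit on the earliest predictor of reward;
# with a short one, early cues are no longer eligible at reward and
# credit shifts to the cues closest to it, producing a ramp. The target's
# own (self) credit is what its predecessors since its previous
# occurrence leave unexplained, so reward responses shrink as cue-reward
# contingencies grow.
.anccr_credits <- function(M, Mbar, R, last_t, prev_occ_j, j, params) {
  K <- nrow(M)
  w <- params$w
  nc_j <- .net_contingency(M, Mbar, j, seq_len(K), w)

  # occurrence times used for ordering; the target's own slot uses its
  # previous occurrence
  occ <- last_t
  occ[j] <- prev_occ_j

  a <- numeric(K)
  others <- setdiff(seq_len(K), j)
  others <- others[is.finite(occ[others])]
  others <- others[order(occ[others])]
  for (k in others) {
    prior <- others[occ[others] < occ[k]]
    adj <- 0
    if (length(prior)) {
      nc_mk <- .net_contingency(M, Mbar, k, prior, w)
      adj <- sum(pmax(pmin(nc_mk, 1), 0) * a[prior])
    }
    a[k] <- nc_j[k] * R[j] - adj
  }
  if (is.finite(occ[j])) {
    since <- others[occ[others] > occ[j]]
    adj <- if (length(since)) {
      sum(pmax(pmin(nc_j[since], 1), 0) * a[since])
    } else 0
    a[j] <- nc_j[j] * R[j] - adj
  } else {
    a[j] <- nc_j[j] * R[j]
  }
  a
}

.compose_dopamine <- function(ANCCR, meaningful, b, j, reward_k, params) {
  out <- sum(ANCCR[j, meaningful])
  if (params$add_innate_to_reward && j == reward_k) out <- out + b[j]
  out
}

#' Dopamine response composed from a model state
#'
#' Reads out the dopamine response the model would emit for an occurrence
#' of `label` given a state (as returned in `run_anccr()$state`): the sum
#' of the event's stored adjusted net contingencies toward all meaningful
#' targets, plus the reward's innate value when configured.
#'
#' @param state A state list from [run_anccr()].
#' @param label Event label that just occurred.
#' @param params An [anccr_params()].
#' @return Scalar dopamine response.
#' @export
compose_dopamine_responses <- function(state, label, params = anccr_params()) {
  j <- match(label, state$labels)
  if (is.na(j)) stop("unknown event label: ", label)
  reward_k <- match("reward", state$labels)
  .compose_dopamine(state$ANCCR, state$meaningful, state$b, j, reward_k, params)
}

#' Run the full ANCCR simulation for a condition
#'
#' Simulates `n_iterations` independent event streams from `config`, runs
#' the ANCCR engine over each, and retains the per-event dopamine responses
#' of the last `n_analysis_trials` trials of each iteration.
#'
#' @param config A [trial_config()] with a consummatory period (simulation
#'   trial structure).
#' @param params An [anccr_params()].
#' @param seed Integer master seed; per-iteration stream seeds are spawned
#'   from it and recorded in the result's `seeds` attribute.
#' @return A data frame of class `anccr_sim` with columns `iteration`,
#'   `trial` (1-based within the analysis window), `label`,
#'   `time_in_trial_s`, `dopamine`.
#' @export
run_simulation <- function(config, params = anccr_params(), seed = 1L) {
  stopifnot(inherits(config, "trial_config"))
  if (config$n_trials < params$n_analysis_trials) {
    stop("stream shorter than n_analysis_trials")
  }
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, params$n_iterations)
  keep_from <- config$n_trials - params$n_analysis_trials + 1L
  pieces <- vector("list", params$n_iterations)
  for (it in seq_len(params$n_iterations)) {
    stream <- build_simulation_stream(config, seed = seeds[it])
    run <- run_anccr(stream, params)
    ev <- run$events
    first_t <- tapply(ev$time_s, ev$trial, min)
    ev$time_in_trial_s <- ev$time_s - first_t[as.character(ev$trial)]
    ev <- ev[ev$trial >= keep_from, ]
    pieces[[it]] <- data.frame(iteration = it,
                               trial = ev$trial - keep_from + 1L,
                               label = ev$label,
                               time_in_trial_s = ev$time_in_trial_s,
                               dopamine = ev$dopamine,
                               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  attr(out, "seeds") <- seeds
  class(out) <- c("anccr_sim", "data.frame")
  out
}

#' Ramp slope and onset response of a simulation result
#'
#' Averages dopamine responses over trials and iterations at each
#' within-trial event time, then fits an ordinary least-squares slope to
#' the iteration-averaged response across event times inside the half-open
#' `window` (the 3-8 s ramp window by default, which excludes the cue
#' onset and offset responses). The onset response is the mean dopamine at
#' the first event of the trial.
#'
#' @param result An `anccr_sim` data frame from [run_simulation()].
#' @param window Two-element numeric, half-open window `[a, b)` of
#'   within-trial event times (s).
#' @return A list: `slope` (response units per s), `onset_response`,
#'   `per_iteration` (data frame with per-iteration slope and onset),
#'   `profile` (mean response per event time).
#' @export
simulation_ramp_metrics <- function(result, window = c(3, 8)) {
  stopifnot(inherits(result, "data.frame"), length(window) == 2)
  tt <- round(result$time_in_trial_s, 6)
  prof <- stats::aggregate(dopamine ~ tt, data.frame(tt = tt,
                                                     dopamine = result$dopamine),
                           mean)
  names(prof) <- c("time_in_trial_s", "dopamine")
  sel <- prof$time_in_trial_s >= window[1] & prof$time_in_trial_s < window[2]
  if (sum(sel) < 2) stop("fewer than 2 event times in the ramp window")
  slope <- .ols_slope(prof$time_in_trial_s[sel], prof$dopamine[sel])
  onset_t <- min(prof$time_in_trial_s)
  onset <- prof$dopamine[prof$time_in_trial_s == onset_t]

  per_it <- do.call(rbind, lapply(split(data.frame(tt = tt,
                                                   dopamine = result$dopamine),
                                        result$iteration), function(d) {
    p <- stats::aggregate(dopamine ~ tt, d, mean)
    s <- p$tt >= window[1] & p$tt < window[2]
    data.frame(slope = .ols_slope(p$tt[s], p$dopamine[s]),
               onset_response = p$dopamine[p$tt == min(p$tt)])
  }))
  per_it$iteration <- as.integer(rownames(per_it))
  rownames(per_it) <- NULL

  list(slope = slope, onset_response = onset,
       per_iteration = per_it[, c("iteration", "slope", "onset_response")],
       profile = prof)
}
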