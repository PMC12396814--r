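# Trial-wise statistics relating ramp slope to ITI history.

.regression_report <- function(fit, n, scope) {
  s <- summary(fit)$coefficients
  structure(
    list(beta = unname(s[2, 1]), intercept = unname(s[1, 1]),
         se = unname(s[2, 2]), p_value = unname(s[2, 4]),
         n = n, scope = scope),
    class = "regression_report"
  )
}

#' @export
print.regression_report <- function(x, ...) {
  cat(sprintf("%s regression: beta = %.4g (SE %.3g), p = %.3g, n = %d\n",
              x$scope, x$beta, x$se, x$p_value, x$n))
  invisible(x)
}

#' Regress ramp slope on the previous inter-trial interval
#'
#' Per-animal OLS of the per-trial ramp slope on the duration of the ITI
#' preceding each trial. A negative beta means a longer preceding ITI
#' weakens the next trial's ramp. Trials without a defined previous ITI
#' (the first of a session) are excluded.
#'
#' @param table A trial table with columns `ramp_slope` and
#'   `previous_iti_s`.
#' @return A `regression_report` (fields `beta`, `intercept`, `se`,
#'   `p_value`, `n`, `scope`).
#' @export
previous_iti_beta <- function(table) {
  d <- table[is.finite(table$ramp_slope) & is.finite(table$previous_iti_s), ]
  if (nrow(d) < 3) stop("need at least 3 trials with a defined previous ITI")
  if (stats::var(d$previous_iti_s) == 0) stop("degenerate previous-ITI variance")
  fit <- stats::lm(ramp_slope ~ previous_iti_s, data = d)
  .regression_report(fit, nrow(d), "per-animal")
}

#' Pooled regression of z-scored ramp slope on previous ITI
#'
#' Ramp slopes are z-scored within each animal (mean 0, SD 1), pooled
#' across animals, and regressed on the previous ITI. Z-scoring per animal
#' removes the effect of variable slope means across animals on the pooled
#' fit. Animals with zero slope variance are excluded with a warning.
#'
#' @param tables A single trial table with an `animal_id` column, or a
#'   list of per-animal trial tables (list names become animal ids).
#' @return A `regression_report` with scope `"pooled"`.
#' @export
pooled_zscore_beta <- function(tables) {
  if (is.data.frame(tables)) {
    if (is.null(tables$animal_id)) stop("table must carry an animal_id column")
    tables <- split(tables, tables$animal_id)
  }
  if (length(tables) < 2) stop("need at least 2 animals to pool")
  pooled <- list()
  for (id in names(tables)) {
    d <- tables[[id]]
    d <- d[is.finite(d$ramp_slope) & is.finite(d$previous_iti_s), ]
    if (nrow(d) < 3 || stats::sd(d$ramp_slope) == 0) {
      warning(sprintf("animal %s excluded (too few trials or zero slope variance)", id))
      next
    }
    d$z_slope <- (d$ramp_slope - mean(d$ramp_slope)) / stats::sd(d$ramp_slope)
    pooled[[id]] <- d[, c("z_slope", "previous_iti_s")]
  }
  if (length(pooled) < 2) stop("fewer than 2 animals usable after exclusion")
  d <- do.call(rbind, pooled)
  fit <- stats::lm(z_slope ~ previous_iti_s, data = d)
  .regression_report(fit, nrow(d), "pooled")
}

#' Change-in-ITI versus change-in-slope analysis
#'
#' For consecutive trial pairs, relates the change in the preceding ITI
#' (`delta_iti = previous_iti[i] - previous_iti[i-1]`) to the change in
#' ramp slope (`delta_slope = slope[i] - slope[i-1]`): an OLS beta, plus
#' mean `delta_slope` for clear ITI decreases (`delta_iti <
#' -category_threshold_s`) and clear increases (`delta_iti >
#' category_threshold_s`).
#'
#' @param table Trial table with `trial_index`, `ramp_slope`,
#'   `previous_iti_s`.
#' @param category_threshold_s Category cut in seconds (default 1).
#' @return A list: `beta_delta`, `se`, `p_value`, `n`,
#'   `mean_delta_slope_decrease`, `mean_delta_slope_increase` (the latter
#'   two `NA` when a category is empty), and the `pairs` data frame.
#' @export
delta_iti_analysis <- function(table, category_threshold_s = 1) {
  d <- table[order(table$trial_index), ]
  ok <- is.finite(d$ramp_slope) & is.finite(d$previous_iti_s)
  d <- d[ok, ]
  consec <- which(diff(d$trial_index) == 1)
  if (length(consec) < 2) stop("no consecutive trial pairs available")
  i2 <- consec + 1
  pairs <- data.frame(
    delta_iti = d$previous_iti_s[i2] - d$previous_iti_s[consec],
    delta_slope = d$ramp_slope[i2] - d$ramp_slope[consec]
  )
  fit <- stats::lm(delta_slope ~ delta_iti, data = pairs)
  s <- summary(fit)$coefficients
  dec <- pairs$delta_slope[pairs$delta_iti < -category_threshold_s]
  inc <- pairs$delta_slope[pairs$delta_iti > category_threshold_s]
  list(
    beta_delta = unname(s[2, 1]), se = unname(s[2, 2]),
    p_value = unname(s[2, 4]), n = nrow(pairs),
    mean_delta_slope_decrease = if (length(dec)) mean(dec) else NA_real_,
    mean_delta_slope_increase = if (length(inc)) mean(inc) else NA_real_,
    pairs = pairs
  )
}

#' Regress ramp slope on the average of several preceding ITIs
#'
#' Broader history variant: each trial's regressor is the mean of the
#' `k_back` ITIs preceding it (its own previous ITI and the `k_back - 1`
#' before that). Trials lacking a full history are dropped. `k_back = 1`
#' reduces to [previous_iti_beta()].
#'
#' @param table Trial table with `trial_index`, `ramp_slope`,
#'   `previous_iti_s`.
#' @param k_back Number of preceding ITIs to average, `>= 1`.
#' @return A `regression_report`.
#' @export
average_prev_iti_beta <- function(table, k_back) {
  stopifnot(k_back >= 1)
  d <- table[order(table$trial_index), ]
  if (k_back >= nrow(d)) stop("k_back exceeds the session length")
  n <- nrow(d)
  avg <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i < k_back) next
    h <- d$previous_iti_s[(i - k_back + 1):i]
    if (all(is.finite(h)) &&
        all(diff(d$trial_index[(i - k_back + 1):i]) == 1)) {
      avg[i] <- mean(h)
    }
  }
  keep <- is.finite(avg) & is.finite(d$ramp_slope)
  if (sum(keep) < 3) stop("too few trials with a full ITI history")
  fit <- stats::lm(d$ramp_slope[keep] ~ avg[keep])
  .regression_report(fit, sum(keep), sprintf("per-animal (k_back=%d)", k_back))
}

#' Remove inter-reward-interval outliers
#'
#' Drops values more than `k_sd` standard deviations from the mean, with
#' both mean and SD computed once on the original distribution (population
#' SD; single pass, no re-estimation after removal).
#'
#' @param iris Numeric IRI values (s), at least 2.
#' @param k_sd Cutoff in standard deviations (default 3).
#' @return The retained values, in their original order.
#' @export
filter_iri_outliers <- function(iris, k_sd = 3) {
  stopifnot(length(iris) >= 2)
  m <- mean(iris)
  s <- sqrt(mean((iris - m)^2))
  iris[abs(iris - m) <= k_sd * s]
}

#' Compare a metric between two conditions across animals
#'
#' Two-sided t test on per-animal values (paired by default, matching the
#' within-animal condition switches of the task designs).
#'
#' @param per_animal_values_a,per_animal_values_b Numeric vectors of
#'   per-animal means; matched by position when `paired`.
#' @param paired Paired test (default `TRUE`).
#' @return A list: `statistic`, `p_value`, `n`, `mean_difference`,
#'   `method`.
#' @export
condition_comparison <- function(per_animal_values_a, per_animal_values_b,
                                 paired = TRUE) {
  if (paired && length(per_animal_values_a) != length(per_animal_values_b)) {
    stop("paired comparison requires matched animals")
  }
  if (min(length(per_animal_values_a), length(per_animal_values_b)) < 2) {
    stop("need at least 2 animals per group")
  }
  degenerate <- if (paired) {
    stats::sd(per_animal_values_a - per_animal_values_b) == 0
  } else {
    stats::sd(per_animal_values_a) == 0 && stats::sd(per_animal_values_b) == 0
  }
  if (degenerate) {
    d <- mean(per_animal_values_a) - mean(per_animal_values_b)
    return(list(statistic = if (d == 0) 0 else sign(d) * Inf,
                p_value = if (d == 0) 1 else 0,
                n = if (paired) length(per_animal_values_a)
                    else c(length(per_animal_values_a),
                           length(per_animal_values_b)),
                mean_difference = d,
                method = sprintf("degenerate (zero-variance) %s comparison",
                                 if (paired) "paired" else "unpaired")))
  }
  tt <- stats::t.test(per_animal_values_a, per_animal_values_b,
                      paired = paired)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       n = if (paired) length(per_animal_values_a)
           else c(length(per_animal_values_a), length(per_animal_values_b)),
       mean_difference = mean(per_animal_values_a) - mean(per_animal_values_b),
       method = tt$method)
}
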