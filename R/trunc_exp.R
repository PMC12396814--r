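#' Truncated-exponential inter-trial-interval specification
#'
#' Inter-trial intervals (ITIs) in the tasks modelled here are drawn from an
#' exponential distribution truncated to a closed support `[min_s, max_s]`.
#' Task descriptions state only the support and the mean, never the rate, so
#' the rate is recovered numerically by [calibrate_truncated_exponential()].
#'
#' @param min_s,max_s Support bounds in seconds, `0 <= min_s < max_s`.
#' @param target_mean_s Desired mean of the truncated distribution (s).
#' @param rate Exponential rate parameter (1/s), or `NULL` for an
#'   uncalibrated specification (sampling from one is an error).
#' @return An object of class `trunc_exp_spec`.
#' @seealso [calibrate_truncated_exponential()], [sample_itis()]
#' @export
trunc_exp_spec <- function(min_s, max_s, target_mean_s, rate = NULL) {
  stopifnot(is.numeric(min_s), is.numeric(max_s), is.numeric(target_mean_s))
  if (!(min_s >= 0 && min_s < max_s)) {
    stop("invalid support: need 0 <= min_s < max_s")
  }
  mid <- (min_s + max_s) / 2
  if (!(target_mean_s > min_s && target_mean_s < mid)) {
    stop(sprintf(
      "infeasible target mean %.4g s: a truncated exponential on [%g, %g] s can only have a mean in the open interval (%g, %g) s",
      target_mean_s, min_s, max_s, min_s, mid
    ))
  }
  if (!is.null(rate) && !(is.numeric(rate) && rate > 0)) {
    stop("rate must be a positive number or NULL")
  }
  structure(
    list(min_s = min_s, max_s = max_s, target_mean_s = target_mean_s,
         rate = rate),
    class = "trunc_exp_spec"
  )
}

#' @export
print.trunc_exp_spec <- function(x, ...) {
  cat(sprintf(
    "Truncated exponential ITI spec: support [%g, %g] s, target mean %g s, rate %s\n",
    x$min_s, x$max_s, x$target_mean_s,
    if (is.null(x$rate)) "<uncalibrated>" else sprintf("%.6g /s", x$rate)
  ))
  invisible(x)
}

#' Mean of an exponential distribution truncated to a closed interval
#'
#' Closed form: for rate \eqn{\lambda} on support \eqn{[a, b]} with
#' \eqn{d = b - a}, the mean is
#' \eqn{a + 1/\lambda - d / (e^{\lambda d} - 1)}, which decreases
#' monotonically from the midpoint \eqn{(a+b)/2} (as \eqn{\lambda \to 0})
#' to \eqn{a} (as \eqn{\lambda \to \infty}).
#'
#' @param rate Exponential rate (1/s), positive.
#' @param min_s,max_s Support bounds (s).
#' @return Mean of the truncated distribution (s).
#' @export
truncated_exponential_mean <- function(rate, min_s, max_s) {
  stopifnot(rate > 0, min_s < max_s)
  d <- max_s - min_s
  ld <- rate * d
  if (ld < 1e-6) {
    # series expansion, avoids catastrophic cancellation at tiny rates
    return(min_s + d / 2 - rate * d^2 / 12)
  }
  min_s + 1 / rate - d / expm1(ld)
}

#' Calibrate a truncated exponential to a stated mean
#'
#' Solves for the rate such that the truncated mean matches
#' `target_mean_s` to better than 1e-6 s (root bracketing plus
#' [stats::uniroot()]). The feasibility condition is
#' `min_s < target_mean_s < (min_s + max_s) / 2`: a truncated exponential
#' has a decreasing density, so its mean always lies below the support
#' midpoint.
#'
#' @inheritParams trunc_exp_spec
#' @return A calibrated `trunc_exp_spec` (with `rate` filled in).
#' @examples
#' calibrate_truncated_exponential(6, 12, 8)   # short-ITI Pavlovian spec
#' calibrate_truncated_exponential(6, 186, 55) # long-ITI Pavlovian spec
#' @export
calibrate_truncated_exponential <- function(min_s, max_s, target_mean_s) {
  spec <- trunc_exp_spec(min_s, max_s, target_mean_s)
  f <- function(rate) truncated_exponential_mean(rate, min_s, max_s) - target_mean_s
  lo <- 1e-10
  hi <- 1
  while (f(hi) > 0) hi <- hi * 2
  root <- stats::uniroot(f, lower = lo, upper = hi, tol = 1e-14)
  spec$rate <- root$root
  achieved <- truncated_exponential_mean(spec$rate, min_s, max_s)
  if (abs(achieved - target_mean_s) >= 1e-6) {
    stop("calibration failed to reach the target mean within 1e-6 s")
  }
  spec
}

#' Draw inter-trial intervals from a calibrated truncated exponential
#'
#' Sampling is by inversion of the truncated CDF, so every draw lies in
#' `[min_s, max_s]` and results are reproducible given `seed`.
#'
#' @param spec A calibrated [trunc_exp_spec()].
#' @param n Number of draws, `n >= 1`.
#' @param seed Optional integer seed (applied with [set.seed()]).
#' @return Numeric vector of `n` durations in seconds.
#' @export
sample_itis <- function(spec, n, seed = NULL) {
  if (!inherits(spec, "trunc_exp_spec")) stop("spec must be a trunc_exp_spec")
  if (is.null(spec$rate)) stop("uncalibrated spec: call calibrate_truncated_exponential() first")
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  u <- stats::runif(n)
  d <- spec$max_s - spec$min_s
  # inverse CDF of Exp(rate) restricted to [min, max]
  spec$min_s - log1p(-u * (-expm1(-spec$rate * d))) / spec$rate
}

#' Pre-calibrated ITI specifications for the study's conditions
#'
#' @param name One of `"short"` (6-12 s, mean 8 s), `"long"` (6-186 s,
#'   mean 55 s), `"vr_med"` (6-90 s, mean 28 s), `"vr_long"` (6-186 s,
#'   mean 62 s), `"vr_short"` (identical to `"short"`).
#' @return A calibrated `trunc_exp_spec`.
#' @export
iti_spec_preset <- function(name = c("short", "long", "vr_med", "vr_long", "vr_short")) {
  name <- match.arg(name)
  switch(name,
    short    = calibrate_truncated_exponential(6, 12, 8),
    long     = calibrate_truncated_exponential(6, 186, 55),
    vr_med   = calibrate_truncated_exponential(6, 90, 28),
    vr_long  = calibrate_truncated_exponential(6, 186, 62),
    vr_short = calibrate_truncated_exponential(6, 12, 8)
  )
}
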