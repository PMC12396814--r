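# Small internal helpers shared across modules.

# OLS slope of y on x; assumes length >= 2 and var(x) > 0.
.ols_slope <- function(x, y) {
  mx <- mean(x)
  sum((x - mx) * (y - mean(y))) / sum((x - mx)^2)
}

# Logical index of t in the half-open window [a, b).
.in_window <- function(t, a, b) {
  t >= a & t < b
}

# Integer indices of the regular grid t_i = (i - 1) * h, i = 1..n, that
# fall in the half-open window [a, b). O(1) alternative to .in_window for
# generators working on large uniform grids.
.grid_window_idx <- function(n, h, a, b) {
  lo <- max(1L, as.integer(ceiling(a / h - 1e-9)) + 1L)
  hi <- min(n, as.integer(ceiling(b / h - 1e-9)))
  if (lo > hi) integer(0) else lo:hi
}

# Adler-32-style checksum of a character scalar; used to detect manifest
# tampering without a cryptographic dependency.
.text_checksum <- function(txt) {
  bytes <- as.numeric(utf8ToInt(txt))
  if (length(bytes) == 0) return(1)
  cs <- cumsum(bytes)
  n <- length(bytes)
  a <- (1 + cs[n]) %% 65521
  b <- (n + sum(cs)) %% 65521
  b * 65536 + a
}
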