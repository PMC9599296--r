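# Internal numerical helpers shared across modules.

# Analytic signal via the frequency-domain construction: zero out negative
# frequencies, double positive ones, inverse-transform.
analytic_signal <- function(x) {
  n <- length(x)
  if (n < 2) stop("series too short for the analytic signal")
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

instantaneous_phase <- function(x) Arg(analytic_signal(x))

envelope <- function(x) Mod(analytic_signal(x))

# Zero-phase band-pass (4th-order Butterworth per pass, forward-backward).
# Filter transients are suppressed by reflective padding (`pad` seconds on each
# side, dropped afterwards) so no recording samples are consumed.
bandpass <- function(x, low, high, fs, order = 4, pad = 1) {
  if (high >= fs / 2) stop("band edge at or above Nyquist (", fs / 2, " Hz)")
  if (low <= 0 || low >= high) stop("invalid band edges")
  np <- min(length(x) - 1L, round(pad * fs))
  xp <- c(rev(x[seq_len(np) + 1L]), x, rev(x[length(x) - seq_len(np)]))
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  y <- signal::filtfilt(bf, xp)
  y[np + seq_along(x)]
}

# Deterministic child seed (kept well below 2^31).
child_seed <- function(seed, i) {
  (as.numeric(seed) * 1000003 + as.numeric(i) * 7919) %% 2147483629
}

# Lag a series by d samples (d >= 0: delayed copy, front filled by wrap-around
# of the series' own start to keep length and stationarity).
lag_series <- function(x, d) {
  n <- length(x)
  d <- as.integer(d)
  if (d == 0) return(x)
  if (abs(d) >= n) stop("lag exceeds series length")
  if (d > 0) c(x[(n - d + 1):n], x[1:(n - d)]) else c(x[(-d + 1):n], x[1:(-d)])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
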