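# Shared signal-processing primitives: analytic signal, zero-phase FIR
# application, spectra. Kept internal; user-facing wrappers live in the
# preprocessing and phase modules.

# Analytic signal via the frequency-domain construction: double positive
# frequencies, zero negative ones. Single pass over the full trace.
analytic_signal <- function(x) {
  n <- length(x)
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

# Apply a symmetric (linear-phase) FIR kernel with exact zero-phase result:
# circular FFT convolution followed by compensation of the (length-1)/2
# group delay. Circular edges keep the filter exactly linear in the DC
# component (so filtering and demeaning commute); the first/last
# filter-length samples are wrap-contaminated and callers flag them
# unusable where that matters.
fir_apply_zerophase <- function(x, h) {
  nh <- length(h)
  if (nh %% 2 == 0) stop("kernel length must be odd (even order)", call. = FALSE)
  n <- length(x)
  if (n < nh) stop("trace shorter than the filter kernel", call. = FALSE)
  nfft <- stats::nextn(n + nh - 1, 2)
  X <- stats::fft(c(x, numeric(nfft - n)))
  H <- stats::fft(c(h, numeric(nfft - nh)))
  y <- Re(stats::fft(X * H, inverse = TRUE)) / nfft
  # fold the linear-convolution tail back onto the head -> circular result
  tail_len <- nh - 1
  y[seq_len(tail_len)] <- y[seq_len(tail_len)] + y[n + seq_len(tail_len)]
  y <- y[seq_len(n)]
  delay <- (nh - 1) / 2
  c(y[(delay + 1):n], y[seq_len(delay)])
}

# Multi-notch band-stop kernel (fir2 arbitrary-response design).
design_bandstop <- function(fs, stop_bands, order = NULL) {
  if (is.null(order)) order <- round(fs)
  if (order %% 2 == 1) order <- order + 1
  nyq <- fs / 2
  f <- c(0)
  m <- c(1)
  for (b in stop_bands) {
    f <- c(f, (b[1] - 0.5) / nyq, b[1] / nyq, b[2] / nyq, (b[2] + 0.5) / nyq)
    m <- c(m, 1, 0, 0, 1)
  }
  f <- c(f, 1); m <- c(m, 1)
  as.numeric(signal::fir2(order, f, m))
}

design_bandpass <- function(fs, lo, hi, order) {
  if (order %% 2 == 1) order <- order + 1
  as.numeric(signal::fir1(order, c(lo, hi) / (fs / 2), type = "pass"))
}

# One-sided periodogram with Hann taper; returns power at frequencies f.
hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))

periodogram_power <- function(x, fs) {
  n <- length(x)
  X <- stats::fft(x)
  p <- Mod(X)^2 / n
  k <- seq_len(floor(n / 2) + 1)
  list(freq = (k - 1) * fs / n, power = p[k])
}

# Least-squares log-log spectral slope over [f_lo, f_hi].
loglog_slope <- function(x, fs, f_lo = 1, f_hi = 40) {
  pg <- periodogram_power(x, fs)
  keep <- pg$freq >= f_lo & pg$freq <= f_hi & pg$power > 0
  stats::coef(stats::lm(log10(pg$power[keep]) ~ log10(pg$freq[keep])))[[2]]
}
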