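# Broadband (1-10 Hz) generalized phase: FIR bandpass, analytic signal,
# replacement of sub-cutoff / reversed phase-progression epochs by
# shape-preserving cubic interpolation, and nearest-sample spike annotation.

# cached bandpass kernels keyed by (fs, lo, hi, order)
.kernel_cache <- new.env(parent = emptyenv())

theta_kernel <- function(fs, lo, hi, order) {
  key <- paste(fs, lo, hi, order, sep = "_")
  if (is.null(.kernel_cache[[key]])) {
    .kernel_cache[[key]] <- design_bandpass(fs, lo, hi, order)
  }
  .kernel_cache[[key]]
}

bandpass_theta_vector <- function(x, fs, lo = 1, hi = 10, order = NULL) {
  if (is.null(order)) order <- round(6000 * fs / 2000) # spec'd at 2 kHz
  h <- theta_kernel(fs, lo, hi, order)
  fir_apply_zerophase(x - mean(x), h)
}

#' Broadband theta bandpass (1-10 Hz)
#'
#' Zero-phase FIR filtering in the broad theta range spanning both low
#' (1-5 Hz) and high (6-10 Hz) human theta. The default order of 6000 taps
#' is specified at 2 kHz and scaled proportionally at other rates. The
#' filter removes DC and low-frequency drifts that would otherwise shift the
#' analytic signal in the complex plane and distort phase estimates; group
#' delay is fully compensated so theta features stay aligned with the raw
#' trace.
#'
#' @param lfp An [lfp_trace()].
#' @param lo,hi Passband edges, Hz.
#' @param order FIR order (default 6000 x fs/2000).
#' @return An [lfp_trace()] holding the filtered samples.
#' @export
bandpass_theta <- function(lfp, lo = 1, hi = 10, order = NULL) {
  stopifnot(inherits(lfp, "lfp_trace"))
  if (is.null(order)) order <- round(6000 * lfp$fs / 2000)
  if (length(lfp$samples) < 3 * order) {
    stop("trace shorter than 3x the filter length", call. = FALSE)
  }
  lfp$samples <- bandpass_theta_vector(lfp$samples, lfp$fs, lo, hi, order)
  lfp
}

#' Generalized phase of a theta-filtered trace
#'
#' Computes the analytic signal via the Hilbert transform and takes its
#' angle as the phase (convention: 0 at signal peaks, +/-pi at troughs) and
#' its squared magnitude as instantaneous power. Because the band is broad,
#' low-amplitude epochs can show phase progression slower than the low band
#' edge or even reversed (negative instantaneous frequency); those epochs
#' are detected from the centred-difference instantaneous frequency of the
#' unwrapped phase, removed, and bridged with shape-preserving piecewise
#' cubic (PCHIP) interpolation through the neighbouring valid samples before
#' rewrapping. `interp_mask` records exactly which samples were replaced.
#'
#' @param filtered An [lfp_trace()] from [bandpass_theta()] (zero-centred).
#' @param min_freq Lower phase-progression cutoff, Hz (default 1).
#' @return A `phase_series` list: `phase` (radians in (-pi, pi]),
#'   `magnitude`, `power`, `interp_mask`, `fs`.
#' @export
generalized_phase <- function(filtered, min_freq = 1) {
  stopifnot(inherits(filtered, "lfp_trace"))
  x <- filtered$samples
  fs <- filtered$fs
  if (all(x == 0)) stop("all-zero input; phase undefined", call. = FALSE)
  a <- analytic_signal(x)
  mag <- Mod(a)
  ph <- Arg(a)
  up <- unwrap_phase(ph)
  n <- length(up)
  # instantaneous frequency: centred differences, forward/backward at edges
  ifreq <- numeric(n)
  ifreq[2:(n - 1)] <- (up[3:n] - up[1:(n - 2)]) / 2
  ifreq[1] <- up[2] - up[1]
  ifreq[n] <- up[n] - up[n - 1]
  ifreq <- ifreq * fs / (2 * pi)
  bad <- ifreq < min_freq
  # a reversal leaves the unwrapped phase below its pre-epoch level; extend
  # each marked epoch until the phase re-attains that level so interpolation
  # bridges it monotonically
  r <- rle(bad)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (k in which(r$values)) {
    s <- starts[k]
    if (s == 1) next
    v <- up[s - 1]
    j <- ends[k] + 1
    while (j <= n && up[j] <= v) {
      bad[j] <- TRUE
      j <- j + 1
    }
  }
  if (any(bad) && !all(bad)) {
    good <- which(!bad)
    interior <- bad & seq_len(n) > good[1] & seq_len(n) < good[length(good)]
    if (any(interior)) {
      # Fritsch-Carlson monotone Hermite spline = shape-preserving PCHIP
      fn <- stats::splinefun(good, up[good], method = "monoH.FC")
      up[interior] <- fn(which(interior))
    }
    # edges: hold the nearest valid phase trend (linear extrapolation)
    if (good[1] > 1) {
      g1 <- good[1]
      slope <- if (length(good) > 1) {
        (up[good[2]] - up[g1]) / (good[2] - g1)
      } else 2 * pi * min_freq / fs
      up[seq_len(g1 - 1)] <- up[g1] - slope * (g1 - seq_len(g1 - 1))
    }
    gl <- good[length(good)]
    if (gl < n) {
      slope <- if (length(good) > 1) {
        (up[gl] - up[good[length(good) - 1]]) / (gl - good[length(good) - 1])
      } else 2 * pi * min_freq / fs
      up[(gl + 1):n] <- up[gl] + slope * (seq_len(n - gl))
    }
  }
  # untouched samples keep their analytic phase bitwise; only marked
  # samples receive interpolated (rewrapped) values
  out_phase <- ph
  out_phase[bad] <- wrap_pi(up[bad])
  structure(list(
    phase = out_phase, magnitude = mag, power = mag^2,
    interp_mask = bad, fs = fs
  ), class = "phase_series")
}

unwrap_phase <- function(p) {
  d <- diff(p)
  jumps <- round(d / (2 * pi))
  c(p[1], p[1] + cumsum(d - 2 * pi * jumps))
}

#' @export
print.phase_series <- function(x, ...) {
  cat(sprintf("<phase_series> %d samples @ %g Hz; %.2f%% interpolated\n",
              length(x$phase), x$fs, 100 * mean(x$interp_mask)))
  invisible(x)
}

#' Annotate spikes with their theta phase and power
#'
#' Maps each spike to its temporally closest LFP sample (ties broken toward
#' the earlier sample) and records that sample's generalized phase,
#' instantaneous power and log10 power. Spikes inside artifact intervals or
#' outside the trace are dropped (counts reported via message).
#'
#' @param spike_times Numeric spike times, seconds.
#' @param phase_series A [generalized_phase()] result.
#' @param artifact_mask Optional `artifact_mask` (half-open sample intervals).
#' @param unit_id Optional unit label carried into the table.
#' @return A `spike_phase_table` tibble: `unit_id`, `time`, `sample`,
#'   `phase`, `power`, `log_power`, `interp`.
#' @export
assign_spikes <- function(spike_times, phase_series, artifact_mask = NULL,
                          unit_id = "u1") {
  stopifnot(inherits(phase_series, "phase_series"))
  n <- length(phase_series$phase)
  fs <- phase_series$fs
  # nearest sample; exact midpoints round toward the earlier sample
  samp <- floor(spike_times * fs + 0.5 + 1e-9)
  frac <- spike_times * fs - floor(spike_times * fs)
  samp[abs(frac - 0.5) < 1e-9] <- floor(spike_times[abs(frac - 0.5) < 1e-9] * fs)
  samp <- samp + 1L
  inside <- samp >= 1L & samp <= n
  if (any(!inside)) message(sum(!inside), " spike(s) outside trace dropped")
  samp <- samp[inside]
  t <- spike_times[inside]
  if (!is.null(artifact_mask) && nrow(artifact_mask) > 0) {
    in_art <- rep(FALSE, length(samp))
    for (i in seq_len(nrow(artifact_mask))) {
      in_art <- in_art | (samp >= artifact_mask$start[i] &
                            samp < artifact_mask$end[i])
    }
    samp <- samp[!in_art]; t <- t[!in_art]
  }
  tibble::tibble(
    unit_id = unit_id,
    time = t,
    sample = as.integer(samp),
    phase = phase_series$phase[samp],
    power = phase_series$power[samp],
    log_power = log10(phase_series$power[samp]),
    interp = phase_series$interp_mask[samp]
  )
}
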