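# Spike-field coherence: spike-triggered LFP segments at 250 Hz, multitaper
# spectra with Slepian tapers (4 Hz smoothing), and the STA-power-over-mean-
# power ratio per frequency, with matched-spike-count subsampling for
# condition contrasts.

#' Spike-triggered LFP segments
#'
#' Cuts a 1-s window (500 ms before and after each spike) from the cleaned
#' LFP, antialias-resampled to 250 Hz (251 samples, centre included).
#' Spikes closer than the half-window to either trace end are dropped.
#'
#' @param lfp A cleaned [lfp_trace()].
#' @param spike_times Spike times, seconds.
#' @param halfwin_s Half-window, seconds (default 0.5).
#' @param target_fs Segment sampling rate, Hz (default 250).
#' @return A spikes x samples numeric matrix (attribute `fs`).
#' @export
spike_triggered_segments <- function(lfp, spike_times, halfwin_s = 0.5,
                                     target_fs = 250) {
  stopifnot(inherits(lfp, "lfp_trace"))
  dur <- duration_s(lfp)
  ok <- spike_times >= halfwin_s & spike_times <= dur - halfwin_s
  if (sum(!ok) > 0) message(sum(!ok), " spike(s) too close to trace edges dropped")
  st <- spike_times[ok]
  if (length(st) == 0) stop("no usable spikes", call. = FALSE)
  low <- resample_trace(lfp, target_fs)
  half <- round(halfwin_s * target_fs)
  ctr <- round(st * target_fs) # resampled sample j sits at time j/target_fs
  n <- length(low$samples)
  ok2 <- ctr - half >= 1 & ctr + half <= n
  ctr <- ctr[ok2]
  seg <- t(vapply(ctr, function(c_) low$samples[(c_ - half):(c_ + half)],
                  numeric(2 * half + 1)))
  attr(seg, "fs") <- target_fs
  seg
}

# Slepian (DPSS) tapers from the standard symmetric tridiagonal eigenproblem
dpss_tapers <- function(n, nw, k) {
  w <- nw / n
  d <- ((n - 1 - 2 * (0:(n - 1))) / 2)^2 * cos(2 * pi * w)
  e <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  A <- matrix(0, n, n)
  diag(A) <- d
  A[cbind(1:(n - 1), 2:n)] <- e
  A[cbind(2:n, 1:(n - 1))] <- e
  eig <- eigen(A, symmetric = TRUE)
  v <- eig$vectors[, seq_len(k), drop = FALSE]
  # normalise and fix sign (positive mean for symmetric tapers)
  for (j in seq_len(k)) {
    v[, j] <- v[, j] / sqrt(sum(v[, j]^2))
    if (sum(v[, j]) < 0) v[, j] <- -v[, j]
  }
  v
}

.dpss_cache <- new.env(parent = emptyenv())

multitaper_power <- function(seg, fs, freqs, nw = 4, k = 7) {
  n <- ncol(seg)
  key <- paste(n, nw, k, sep = "_")
  if (is.null(.dpss_cache[[key]])) .dpss_cache[[key]] <- dpss_tapers(n, nw, k)
  tp <- .dpss_cache[[key]]
  nfft <- 2^ceiling(log2(4 * n))
  fbin <- round(freqs / fs * nfft) + 1L
  pow <- matrix(0, nrow = nrow(seg), ncol = length(freqs))
  for (j in seq_len(k)) {
    tap <- matrix(tp[, j], nrow = nrow(seg), ncol = n, byrow = TRUE) * seg
    X <- t(apply(tap, 1, function(r) stats::fft(c(r, numeric(nfft - n)))))
    if (nrow(seg) == 1) X <- matrix(X, nrow = 1)
    pow <- pow + Mod(X[, fbin, drop = FALSE])^2
  }
  pow / k
}

#' Spike-field coherence spectrum
#'
#' SFC(f) = 100 * P_STA(f) / mean_i P_i(f): the percentage of the power of
#' the spike-triggered average relative to the mean power of the individual
#' spike-centred LFP segments, per frequency. Numerator and denominator go
#' through the identical multitaper path (Slepian tapers, time-bandwidth 4
#' from the 1-s window and 4 Hz smoothing, 7 tapers), so SFC lies in
#' [0, 100]% and equals 100% when all segments are identical.
#'
#' @param segments Matrix from [spike_triggered_segments()].
#' @param freqs Evaluation frequencies, Hz (default 1:100).
#' @return A tibble: `freq`, `sfc` (percent), plus attribute `n_spikes`.
#' @export
sfc_spectrum <- function(segments, freqs = 1:100) {
  if (nrow(segments) < 2) stop("need >= 2 segments", call. = FALSE)
  fs <- attr(segments, "fs")
  if (is.null(fs)) stop("segments lack an `fs` attribute", call. = FALSE)
  sta <- matrix(colMeans(segments), nrow = 1)
  p_sta <- multitaper_power(sta, fs, freqs)[1, ]
  p_seg <- colMeans(multitaper_power(segments, fs, freqs))
  if (any(p_seg <= 0)) stop("degenerate LFP: zero power bin", call. = FALSE)
  out <- tibble::tibble(freq = freqs, sfc = 100 * p_sta / p_seg)
  attr(out, "n_spikes") <- nrow(segments)
  out
}

#' Matched-spike-count SFC contrast
#'
#' Equalises spike counts between two conditions by randomly subsampling the
#' larger condition to the smaller's size; the resulting SFC is averaged
#' over `n_rep` repetitions so both conditions are compared at identical
#' spike counts (SFC is not count-invariant).
#'
#' @param segments_a,segments_b Segment matrices of the two conditions.
#' @param n_rep Subsampling repetitions (default 100).
#' @param freqs Evaluation frequencies, Hz.
#' @param seed Optional integer seed.
#' @return A tibble: `freq`, `sfc_a`, `sfc_b`, with attribute `n_matched`.
#' @export
matched_subsample_contrast <- function(segments_a, segments_b, n_rep = 100,
                                       freqs = 1:100, seed = NULL) {
  if (nrow(segments_a) < 2 || nrow(segments_b) < 2) {
    stop("both segment sets must have >= 2 rows", call. = FALSE)
  }
  if (!is.null(seed)) {
    old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  n_min <- min(nrow(segments_a), nrow(segments_b))
  sub_sfc <- function(seg) {
    fs <- attr(seg, "fs")
    if (nrow(seg) == n_min) return(sfc_spectrum(seg, freqs)$sfc)
    acc <- numeric(length(freqs))
    for (r in seq_len(n_rep)) {
      sub <- seg[sample.int(nrow(seg), n_min), , drop = FALSE]
      attr(sub, "fs") <- fs # matrix subsetting drops attributes
      acc <- acc + sfc_spectrum(sub, freqs)$sfc
    }
    acc / n_rep
  }
  out <- tibble::tibble(freq = freqs,
                        sfc_a = sub_sfc(segments_a),
                        sfc_b = sub_sfc(segments_b))
  attr(out, "n_matched") <- n_min
  out
}
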