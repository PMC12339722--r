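# Time-resolved spectral parameterization: short-time spectra averaged into
# 3-s frames every 500 ms, robust aperiodic (offset/exponent) fits in log-log
# space, iterative Gaussian peak extraction, per-spike slope annotation, and
# the slope-frequency correlation.

#' Time-resolved power spectra
#'
#' Short-time Fourier transform with Hann-tapered 1-s windows at 50%
#' overlap; every 500 ms the spectra of five consecutive windows are
#' averaged, so each frame spans 3 s of signal. Frames overlapping any
#' artifact interval are marked invalid. Spectra are kept at 1-40 Hz with
#' 1 Hz resolution.
#'
#' @param lfp An [lfp_trace()] of at least 3 s.
#' @param artifact_mask Optional `artifact_mask` tibble.
#' @param f_range Hz range retained (default c(1, 40)).
#' @return A `spectral_frames` list: `time` (frame centres, s), `freq`,
#'   `power` (frames x freq matrix), `valid` (logical).
#' @export
timefreq_spectra <- function(lfp, artifact_mask = NULL, f_range = c(1, 40)) {
  stopifnot(inherits(lfp, "lfp_trace"))
  x <- lfp$samples
  fs <- lfp$fs
  n <- length(x)
  if (n < 3 * fs) stop("trace shorter than 3 s", call. = FALSE)
  wlen <- round(fs) # 1 s -> 1 Hz bins
  step <- wlen %/% 2
  starts <- seq(1, n - wlen + 1, by = step)
  win <- hann_window(wlen)
  wnorm <- sum(win^2)
  freq_all <- (0:(wlen %/% 2)) * fs / wlen
  keep <- freq_all >= f_range[1] & freq_all <= f_range[2]
  spec <- matrix(0, nrow = length(starts), ncol = sum(keep))
  for (i in seq_along(starts)) {
    seg <- x[starts[i]:(starts[i] + wlen - 1)]
    # per-window linear detrend: suppresses leakage from sub-window-length
    # fluctuations, which otherwise inflates the lowest bins of steep spectra
    k <- seq_len(wlen)
    seg <- stats::lm.fit(cbind(1, k), seg)$residuals * win
    p <- Mod(stats::fft(seg))^2 / (fs * wnorm)
    spec[i, ] <- p[seq_along(freq_all)][keep]
  }
  # frames: mean of 5 consecutive windows, stepping one window (500 ms)
  n_frames <- length(starts) - 4
  if (n_frames < 1) stop("trace shorter than 3 s", call. = FALSE)
  power <- matrix(0, nrow = n_frames, ncol = sum(keep))
  time <- numeric(n_frames)
  valid <- rep(TRUE, n_frames)
  for (f in seq_len(n_frames)) {
    power[f, ] <- colMeans(spec[f:(f + 4), , drop = FALSE])
    a <- starts[f]; b <- starts[f + 4] + wlen - 1
    time[f] <- ((a + b) / 2 - 1) / fs
    if (!is.null(artifact_mask) && nrow(artifact_mask) > 0) {
      valid[f] <- !any(artifact_mask$start < b + 1 & artifact_mask$end > a)
    }
  }
  structure(list(time = time, freq = freq_all[keep], power = power,
                 valid = valid, fs = fs),
            class = "spectral_frames")
}

#' @export
print.spectral_frames <- function(x, ...) {
  cat(sprintf("<spectral_frames> %d frames (%d valid), %g-%g Hz\n",
              length(x$time), sum(x$valid), min(x$freq), max(x$freq)))
  invisible(x)
}

#' Robust aperiodic (1/f) fit
#'
#' Fits log10 P(f) = b - chi * log10 f over the spectrum by ordinary least
#' squares, then refits using only the points whose residuals fall in the
#' lower half — oscillatory peaks produce large positive residuals and are
#' thereby suppressed. The aperiodic slope in log-log space is -chi; a
#' steeper (more negative) slope means a larger exponent.
#'
#' @param freq Frequencies, Hz.
#' @param power Strictly positive spectral power at `freq`.
#' @return A list: `offset` (b), `exponent` (chi), `rmse` (log10 space).
#' @export
fit_aperiodic <- function(freq, power) {
  if (any(power <= 0)) stop("power must be strictly positive", call. = FALSE)
  lf <- log10(freq)
  lp <- log10(power)
  fit1 <- stats::lm.fit(cbind(1, lf), lp)
  res <- fit1$residuals
  keep <- res <= stats::median(res)
  fit2 <- stats::lm.fit(cbind(1, lf[keep]), lp[keep])
  b <- fit2$coefficients[1]
  chi <- -fit2$coefficients[2]
  pred <- b - chi * lf
  list(offset = unname(b), exponent = unname(chi),
       rmse = sqrt(mean((lp - pred)^2)))
}

gauss_ <- function(f, ctr, hgt, wid) hgt * exp(-(f - ctr)^2 / (2 * wid^2))

#' Iterative Gaussian peak extraction
#'
#' Extracts up to `max_peaks` Gaussians from the flattened spectrum (log10
#' power minus the aperiodic fit), largest residual first. Peaks must have
#' height > `height_min`, SNR (height over the SD of the flattened residual
#' spectrum) > `snr_min` and Gaussian SD within `width_range`; a peak whose
#' centre falls within one SD of a larger peak's centre or within one SD of
#' the frequency edges is discarded.
#'
#' @param freq Frequencies, Hz.
#' @param power Spectral power.
#' @param aperiodic A [fit_aperiodic()] result.
#' @param max_peaks Maximum surviving peaks (default 3).
#' @param snr_min,height_min Acceptance thresholds (defaults 2 and 0.5).
#' @param width_range Gaussian SD bounds, Hz (default c(2, 6)).
#' @return A tibble of peaks: `center`, `height`, `width`.
#' @export
fit_peaks <- function(freq, power, aperiodic, max_peaks = 3, snr_min = 2,
                      height_min = 0.5, width_range = c(2, 6)) {
  flat <- log10(power) - (aperiodic$offset - aperiodic$exponent * log10(freq))
  work <- flat
  cand <- list()
  for (k in seq_len(max_peaks * 2)) { # extract extras; pruning comes after
    i <- which.max(work)
    hgt <- work[i]
    if (hgt <= 0) break
    ctr0 <- freq[i]
    # half-height width guess, clamped to bounds
    above <- work >= hgt / 2
    wl <- i; while (wl > 1 && above[wl - 1]) wl <- wl - 1
    wr <- i; while (wr < length(work) && above[wr + 1]) wr <- wr + 1
    wid0 <- max(width_range[1],
                min(width_range[2], (freq[wr] - freq[wl]) / 2.355))
    opt <- try(stats::optim(
      c(ctr0, hgt, wid0),
      function(p) sum((work - gauss_(freq, p[1], p[2], p[3]))^2),
      method = "L-BFGS-B",
      lower = c(min(freq), 0, width_range[1]),
      upper = c(max(freq), 2 * max(hgt, 1), width_range[2])
    ), silent = TRUE)
    if (inherits(opt, "try-error")) break
    p <- opt$par
    cand[[length(cand) + 1]] <- list(center = p[1], height = p[2], width = p[3])
    work <- work - gauss_(freq, p[1], p[2], p[3])
    if (max(work) < height_min) break
  }
  if (length(cand) == 0) {
    return(tibble::tibble(center = numeric(), height = numeric(),
                          width = numeric()))
  }
  pk <- dplyr::bind_rows(lapply(cand, tibble::as_tibble))
  resid_sd <- stats::sd(work)
  pk <- pk[pk$height > height_min & pk$height / max(resid_sd, 1e-12) > snr_min &
             pk$width >= width_range[1] & pk$width <= width_range[2], ]
  if (nrow(pk) == 0) return(pk)
  # edge rule: centre within one SD of either frequency edge
  pk <- pk[pk$center - pk$width > min(freq) & pk$center + pk$width < max(freq), ]
  if (nrow(pk) <= 1) return(utils::head(pk[order(-pk$height), ], max_peaks))
  # proximity rule: drop a peak within one SD of a larger peak's centre
  pk <- pk[order(-pk$height), ]
  keep <- rep(TRUE, nrow(pk))
  for (i in seq_len(nrow(pk))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(pk))) {
      if (j <= i || !keep[j]) next
      if (abs(pk$center[j] - pk$center[i]) < pk$width[i]) keep[j] <- FALSE
    }
  }
  utils::head(pk[keep, ], max_peaks)
}

#' Parameterize all frames
#'
#' Runs [fit_aperiodic()] (and optionally [fit_peaks()]) on every valid
#' frame of a [timefreq_spectra()] result.
#'
#' @param frames A `spectral_frames` object.
#' @param peaks Also fit Gaussian peaks (default FALSE; slower).
#' @return A tibble: `frame`, `time`, `offset`, `exponent`, `rmse`,
#'   `valid`, and if `peaks`, a list-column `peaks`.
#' @export
fit_frames <- function(frames, peaks = FALSE) {
  stopifnot(inherits(frames, "spectral_frames"))
  out <- purrr::map_dfr(seq_along(frames$time), function(f) {
    if (!frames$valid[f] || any(frames$power[f, ] <= 0)) {
      return(tibble::tibble(frame = f, time = frames$time[f],
                            offset = NA_real_, exponent = NA_real_,
                            rmse = NA_real_, valid = FALSE))
    }
    ap <- fit_aperiodic(frames$freq, frames$power[f, ])
    tibble::tibble(frame = f, time = frames$time[f], offset = ap$offset,
                   exponent = ap$exponent, rmse = ap$rmse, valid = TRUE)
  })
  if (peaks) {
    out$peaks <- purrr::map(seq_along(frames$time), function(f) {
      if (!out$valid[f]) return(NULL)
      ap <- list(offset = out$offset[f], exponent = out$exponent[f])
      fit_peaks(frames$freq, frames$power[f, ], ap)
    })
  }
  out
}

#' Annotate spikes with the aperiodic slope of their time window
#'
#' Each spike inherits the exponent of the frame whose 500 ms step contains
#' it (frame i owns the half-open interval centred on its centre time).
#' Spikes in invalid frames, or outside all frame steps, get NA and are
#' excluded from slope-conditioned analyses.
#'
#' @param spike_table A `spike_phase_table`.
#' @param frame_fits Output of [fit_frames()].
#' @return The table with a numeric `slope_exponent` column.
#' @export
assign_spike_slopes <- function(spike_table, frame_fits) {
  ctr <- frame_fits$time
  step <- if (length(ctr) > 1) ctr[2] - ctr[1] else 0.5
  idx <- floor((spike_table$time - (ctr[1] - step / 2)) / step) + 1
  ok <- idx >= 1 & idx <= nrow(frame_fits)
  slope <- rep(NA_real_, nrow(spike_table))
  slope[ok] <- frame_fits$exponent[idx[ok]]
  slope[ok][!frame_fits$valid[idx[ok]]] <- NA_real_
  spike_table$slope_exponent <- slope
  spike_table
}

#' Correlation between aperiodic slope and theta cycle frequency
#'
#' Per wire: Spearman correlation between each valid frame's exponent and
#' the mean frequency (1/period) of the cycles whose peak falls inside the
#' frame's 3-s span; correlations are averaged per session and a two-sided
#' one-sample t-test is run across sessions.
#'
#' @param session_tables A list (one per session) of tibbles with columns
#'   `wire`, `rho` — or use the helper return of
#'   [slope_frequency_by_wire()] to build them.
#' @return A list: `per_session` (mean rho), `t`, `df`, `p`.
#' @export
slope_frequency_correlation <- function(session_tables) {
  if (length(session_tables) < 2) {
    stop("group test requires >= 2 sessions", call. = FALSE)
  }
  per_session <- vapply(session_tables, function(tb) mean(tb$rho, na.rm = TRUE),
                        numeric(1))
  tt <- stats::t.test(per_session, mu = 0)
  list(per_session = per_session, t = unname(tt$statistic),
       df = unname(tt$parameter), p = tt$p.value)
}

#' Per-wire slope-frequency Spearman correlation
#'
#' @param frame_fits Output of [fit_frames()] for one wire.
#' @param cycles Cycle tibble from [score_cycles()].
#' @param fs Sampling rate, Hz.
#' @param span_s Frame span, seconds (default 3).
#' @return A one-row tibble with `rho` and `n_frames`, or zero rows when
#'   fewer than 3 valid frames have cycles.
#' @export
slope_frequency_by_wire <- function(frame_fits, cycles, fs, span_s = 3) {
  ff <- frame_fits[frame_fits$valid, ]
  if (nrow(ff) < 3 || nrow(cycles) == 0) {
    return(tibble::tibble(rho = numeric(), n_frames = integer()))
  }
  cyc_t <- cycles$peak / fs
  cyc_f <- 1 / cycles$period
  mean_freq <- vapply(ff$time, function(tc) {
    sel <- cyc_t >= tc - span_s / 2 & cyc_t < tc + span_s / 2
    if (!any(sel)) NA_real_ else mean(cyc_f[sel])
  }, numeric(1))
  ok <- is.finite(mean_freq)
  if (sum(ok) < 3) return(tibble::tibble(rho = numeric(), n_frames = integer()))
  rho <- stats::cor(ff$exponent[ok], mean_freq[ok], method = "spearman")
  tibble::tibble(rho = rho, n_frames = sum(ok))
}
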