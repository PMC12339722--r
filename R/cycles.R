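# Cycle-by-cycle oscillation detection: extrema from the generalized phase,
# per-cycle amplitude/period/monotonicity scoring against fixed thresholds,
# and grouping of consecutive oscillatory cycles into bouts.

#' Peaks and troughs from the generalized phase
#'
#' Peaks are placed at upward zero-crossings of the phase (phase 0 = signal
#' peak) and troughs at +/-pi wraps. If the raw crossings repeat without
#' alternation (a phase glitch), the peak with the maximum filtered-trace
#' value is retained and the trough with the minimum value is kept, so the
#' output strictly alternates.
#'
#' @param phase_series A [generalized_phase()] result.
#' @param filtered Numeric filtered trace used for amplitude tie-breaks.
#' @return A list with integer vectors `peaks` and `troughs`, strictly
#'   alternating.
#' @export
find_extrema_from_phase <- function(phase_series, filtered) {
  stopifnot(inherits(phase_series, "phase_series"))
  ph <- phase_series$phase
  n <- length(ph)
  d <- diff(ph)
  # peaks: up-through-zero without wrap; troughs: wrap from +pi to -pi
  peaks <- which(ph[-n] < 0 & ph[-1] >= 0 & d > 0 & d < pi) + 1L
  troughs <- which(d < -pi) + 1L
  ev <- rbind(
    data.frame(idx = peaks, kind = "peak"),
    data.frame(idx = troughs, kind = "trough")
  )
  if (nrow(ev) == 0 || length(peaks) < 2) {
    message("fewer than 2 peaks; empty cycle set")
    return(list(peaks = integer(), troughs = integer()))
  }
  ev <- ev[order(ev$idx), ]
  # enforce alternation: among consecutive same-kind events keep the extreme
  keep_idx <- integer(); keep_kind <- character()
  i <- 1
  while (i <= nrow(ev)) {
    j <- i
    while (j < nrow(ev) && ev$kind[j + 1] == ev$kind[i]) j <- j + 1
    run <- ev$idx[i:j]
    best <- if (ev$kind[i] == "peak") run[which.max(filtered[run])] else run[which.min(filtered[run])]
    keep_idx <- c(keep_idx, best); keep_kind <- c(keep_kind, ev$kind[i])
    i <- j + 1
  }
  list(peaks = keep_idx[keep_kind == "peak"],
       troughs = keep_idx[keep_kind == "trough"])
}

#' Score cycles and detect oscillation bouts
#'
#' Segments the filtered trace into putative cycles lasting from one peak to
#' the next (the trough between defines the decay and rise flanks; edge
#' half-cycles are discarded). Each cycle gets an amplitude (mean of decay
#' and rise excursions), a period, amplitude- and period-consistency scores
#' (min/max ratio against each neighbouring cycle, taking the worse), and a
#' monotonicity score (fraction of same-sign sample-to-sample differences on
#' the flanks). A cycle is oscillatory iff all three scores pass their
#' thresholds and its amplitude exceeds the `amp_percentile`-th percentile
#' of all cycle amplitudes on the wire; runs of at least `min_cycles`
#' oscillatory cycles become bouts whose frequency is n_cycles / duration.
#'
#' @param filtered Numeric filtered trace.
#' @param extrema Output of [find_extrema_from_phase()].
#' @param fs Sampling rate, Hz.
#' @param amp_consistency,period_consistency,monotonicity Score thresholds in
#'   [0, 1] (defaults 0.3 / 0.5 / 0.6).
#' @param min_cycles Minimum cycles per bout (default 2).
#' @param amp_percentile Amplitude percentile floor (default 20).
#' @return A list with `cycles` (tibble) and `bouts` (tibble: `start`,
#'   `end` samples, `n_cycles`, `frequency`).
#' @export
score_cycles <- function(filtered, extrema, fs, amp_consistency = 0.3,
                         period_consistency = 0.5, monotonicity = 0.6,
                         min_cycles = 2, amp_percentile = 20) {
  thr <- c(amp_consistency, period_consistency, monotonicity)
  if (any(thr < 0 | thr > 1)) stop("thresholds must be in [0, 1]", call. = FALSE)
  pk <- extrema$peaks; tr <- extrema$troughs
  empty <- list(
    cycles = tibble::tibble(peak = integer(), next_peak = integer(),
                            trough = integer(), decay = numeric(),
                            rise = numeric(), amplitude = numeric(),
                            period = numeric(), amp_consist = numeric(),
                            period_consist = numeric(), monotonic = numeric(),
                            amp_rank = numeric(), is_oscillatory = logical(),
                            bout_id = integer()),
    bouts = tibble::tibble(start = integer(), end = integer(),
                           n_cycles = integer(), frequency = numeric())
  )
  if (length(pk) < 2) return(empty)
  rows <- list()
  for (i in seq_len(length(pk) - 1)) {
    t_in <- tr[tr > pk[i] & tr < pk[i + 1]]
    if (length(t_in) != 1) next
    decay <- filtered[pk[i]] - filtered[t_in]
    rise <- filtered[pk[i + 1]] - filtered[t_in]
    flank1 <- diff(filtered[pk[i]:t_in])
    flank2 <- diff(filtered[t_in:pk[i + 1]])
    mono <- mean(c(flank1 <= 0, flank2 >= 0))
    rows[[length(rows) + 1]] <- tibble::tibble(
      peak = pk[i], next_peak = pk[i + 1], trough = t_in,
      decay = decay, rise = rise,
      amplitude = (decay + rise) / 2,
      period = (pk[i + 1] - pk[i]) / fs,
      monotonic = mono
    )
  }
  if (length(rows) < 1) return(empty)
  cyc <- dplyr::bind_rows(rows)
  m <- nrow(cyc)
  ratio <- function(a, b) pmin(a, b) / pmax(a, b)
  # amplitude consistency at the flank level (the upstream cycle-by-cycle
  # definition): worst min/max ratio among the flank pairs touching cycle i
  dk <- pmax(cyc$decay, 1e-12); rs <- pmax(cyc$rise, 1e-12)
  within <- ratio(dk, rs)
  prev_pair <- c(NA, ratio(rs[-m], dk[-1]))   # rise_{i-1} vs decay_i
  next_pair <- c(ratio(rs[-m], dk[-1]), NA)   # rise_i vs decay_{i+1}
  cyc$amp_consist <- pmin(within, prev_pair, next_pair, na.rm = TRUE)
  neigh_score <- function(v) {
    prev <- c(NA, ratio(v[-m], v[-1]))
    nxt <- c(ratio(v[-m], v[-1]), NA)
    pmin(prev, nxt, na.rm = TRUE)
  }
  cyc$period_consist <- if (m > 1) neigh_score(cyc$period) else 1
  cyc$amp_rank <- stats::ecdf(cyc$amplitude)(cyc$amplitude) * 100
  amp_floor <- stats::quantile(cyc$amplitude, amp_percentile / 100, names = FALSE)
  # ties at the percentile pass (constant-amplitude signals would otherwise
  # lose an arbitrary 20% of their cycles to numerical noise)
  amp_tol <- 1e-9 * max(abs(cyc$amplitude))
  cyc$is_oscillatory <- cyc$amp_consist >= amp_consistency &
    cyc$period_consist >= period_consistency &
    cyc$monotonic >= monotonicity &
    cyc$amplitude > amp_floor - amp_tol
  # bouts: runs of >= min_cycles contiguous oscillatory cycles
  cyc$bout_id <- NA_integer_
  bouts <- list()
  r <- rle(cyc$is_oscillatory)
  pos <- cumsum(c(1, r$lengths))
  bid <- 0L
  for (k in seq_along(r$lengths)) {
    if (!r$values[k] || r$lengths[k] < min_cycles) next
    i0 <- pos[k]; i1 <- pos[k + 1] - 1
    # contiguity: consecutive cycles must share a peak
    runs <- split_contiguous(cyc, i0, i1)
    for (rr in runs) {
      if (length(rr) < min_cycles) next
      bid <- bid + 1L
      cyc$bout_id[rr] <- bid
      start <- cyc$peak[rr[1]]; end <- cyc$next_peak[rr[length(rr)]]
      nc <- length(rr)
      bouts[[bid]] <- tibble::tibble(
        start = start, end = end, n_cycles = nc,
        frequency = nc / ((end - start) / fs)
      )
    }
  }
  list(cycles = cyc,
       bouts = if (bid > 0) dplyr::bind_rows(bouts) else empty$bouts)
}

split_contiguous <- function(cyc, i0, i1) {
  idx <- i0:i1
  if (length(idx) == 1) return(list(idx))
  brk <- which(cyc$peak[idx[-1]] != cyc$next_peak[idx[-length(idx)]])
  if (length(brk) == 0) return(list(idx))
  split(idx, cumsum(c(0, seq_along(idx[-1]) %in% brk)))
}

#' Oscillation occupancy and frequency summary
#'
#' @param bouts Bout tibble from [score_cycles()].
#' @param n_samples Trace length in samples.
#' @param fs Sampling rate, Hz.
#' @return A list: `occupancy` (fraction of time inside bouts, in [0, 1]),
#'   `mode_freq` (most common integer frequency in 1-10 Hz, NA when no
#'   bouts), `histogram` (tibble of 0.5 Hz bins summing to 1).
#' @export
oscillation_summary <- function(bouts, n_samples, fs) {
  if (nrow(bouts) == 0) {
    return(list(occupancy = 0, mode_freq = NA_real_,
                histogram = tibble::tibble(freq_bin = numeric(),
                                           proportion = numeric())))
  }
  occupancy <- sum(bouts$end - bouts$start) / n_samples
  rounded <- round(bouts$frequency)
  mode_freq <- as.numeric(names(which.max(table(rounded))))
  bin <- floor(bouts$frequency / 0.5) * 0.5
  hist <- dplyr::count(tibble::tibble(freq_bin = bin), .data$freq_bin)
  hist$proportion <- hist$n / sum(hist$n)
  list(occupancy = occupancy, mode_freq = mode_freq,
       histogram = hist[, c("freq_bin", "proportion")])
}

#' Flag spikes occurring inside oscillation bouts
#'
#' Bout intervals are half-open in samples: a spike on the start sample is
#' inside, one on the end sample is not.
#'
#' @param spike_table A `spike_phase_table`.
#' @param bouts Bout tibble from [score_cycles()].
#' @return The table with a logical `in_oscillation` column.
#' @export
flag_spikes_in_oscillation <- function(spike_table, bouts) {
  flag <- rep(FALSE, nrow(spike_table))
  for (i in seq_len(nrow(bouts))) {
    flag <- flag | (spike_table$sample >= bouts$start[i] &
                      spike_table$sample < bouts$end[i])
  }
  spike_table$in_oscillation <- flag
  spike_table
}
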