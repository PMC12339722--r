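# Cycle segmentation and oscillation-bout detection.

test_that("a 4 Hz sinusoid yields ~40 alternating peaks in 10 s", {
  fs <- 2000
  f <- bandpass_theta(fix_sinusoid(4, 10, fs, 10))
  ps <- generalized_phase(f)
  ex <- find_extrema_from_phase(ps, f$samples)
  expect_lte(abs(length(ex$peaks) - 40), 1)
  ev <- sort(c(ex$peaks, ex$troughs))
  kinds <- ifelse(ev %in% ex$peaks, "p", "t")
  expect_true(all(kinds[-1] != kinds[-length(kinds)])) # strict alternation
})

test_that("extrema alternate on every synthetic session wire", {
  ann <- fix_small_session()$annotated
  for (w in ann$wires) {
    ex <- find_extrema_from_phase(w$phase, w$filt$samples)
    ev <- sort(c(ex$peaks, ex$troughs))
    kinds <- ifelse(ev %in% ex$peaks, "p", "t")
    expect_true(all(kinds[-1] != kinds[-length(kinds)]))
  }
})

test_that("repeated same-kind extrema keep the larger peak / deeper trough", {
  # hand-built phase with a wrap glitch producing two candidate peaks
  filtered <- c(0, 1, 0, -1, 0, 2, 0, -2, 0, 1, 0, -1, 0)
  ps <- structure(list(
    phase = c(-0.1, 0.1, 2, -3.1, -0.1, 0.1, 2, -3.1, -0.1, 0.1, 2, -3.1, 0),
    magnitude = rep(1, 13), power = rep(1, 13),
    interp_mask = rep(FALSE, 13), fs = 10), class = "phase_series")
  ex <- find_extrema_from_phase(ps, filtered)
  ev <- sort(c(ex$peaks, ex$troughs))
  kinds <- ifelse(ev %in% ex$peaks, "p", "t")
  expect_true(all(kinds[-1] != kinds[-length(kinds)]))
})

test_that("pure sinusoid: interior cycles oscillatory, bout frequency exact", {
  fs <- 2000
  f <- bandpass_theta(fix_sinusoid(4, 20, fs, 50))
  ps <- generalized_phase(f)
  ex <- find_extrema_from_phase(ps, f$samples)
  cb <- score_cycles(f$samples, ex, fs)
  interior <- cb$cycles[8:(nrow(cb$cycles) - 8), ]
  expect_true(all(interior$is_oscillatory))
  expect_true(all(abs(cb$bouts$frequency - 4) < 0.1))
  # identity: frequency == n_cycles / duration for every bout
  expect_equal(cb$bouts$frequency,
               cb$bouts$n_cycles / ((cb$bouts$end - cb$bouts$start) / fs))
  os <- oscillation_summary(cb$bouts, length(f$samples), fs)
  expect_gt(os$occupancy, 0.9)
  expect_equal(os$mode_freq, 4)
  expect_equal(sum(os$histogram$proportion), 1)
})

test_that("raising thresholds never increases oscillatory-cycle counts", {
  fs <- 2000
  x <- gen_pink_noise(fs * 60, fs, 1, seed = 9) +
    gen_theta_bursts(60, fs, c(3, 5), 10, c(4, 10), amplitude = 2,
                     seed = 10)$trace[1:(fs * 60)]
  f <- bandpass_theta(lfp_trace(x, fs))
  ps <- generalized_phase(f)
  ex <- find_extrema_from_phase(ps, f$samples)
  n_osc <- function(...) sum(score_cycles(f$samples, ex, fs, ...)$cycles$is_oscillatory)
  base <- n_osc()
  expect_lte(n_osc(amp_consistency = 0.5), base)
  expect_lte(n_osc(period_consistency = 0.7), base)
  expect_lte(n_osc(monotonicity = 0.8), base)
  expect_lte(n_osc(amp_percentile = 40), base)
  expect_error(score_cycles(f$samples, ex, fs, monotonicity = 1.2), "\\[0, 1\\]")
})

test_that("a single clean cycle between noise never forms a bout", {
  fs <- 2000
  set.seed(12)
  x <- stats::rnorm(fs * 20, 0, 0.2)
  # one isolated 4 Hz cycle at t = 10 s
  idx <- (10 * fs):(10 * fs + fs / 4 * 2 - 1)
  x[idx] <- x[idx] + sin(2 * pi * 4 * seq(0, 0.5 - 1 / fs, by = 1 / fs))
  f <- bandpass_theta(lfp_trace(x, fs))
  ps <- generalized_phase(f)
  ex <- find_extrema_from_phase(ps, f$samples)
  cb <- score_cycles(f$samples, ex, fs)
  in_cycle <- cb$bouts$start <= max(idx) & cb$bouts$end >= min(idx)
  if (any(in_cycle)) {
    # any bout touching the inserted cycle must contain >= 2 cycles by rule;
    # the isolated cycle alone must not be a bout
    expect_true(all(cb$bouts$n_cycles[in_cycle] >= 2))
  }
  succeed()
})

test_that("spike oscillation flags follow the half-open bout convention", {
  st <- tibble::tibble(sample = c(100L, 199L, 200L, 50L))
  bouts <- tibble::tibble(start = 100L, end = 200L, n_cycles = 3L,
                          frequency = 3)
  out <- flag_spikes_in_oscillation(st, bouts)
  expect_equal(out$in_oscillation, c(TRUE, TRUE, FALSE, FALSE))
  out2 <- flag_spikes_in_oscillation(st, bouts[0, ])
  expect_false(any(out2$in_oscillation))
})
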