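# LFP conditioning: waveform subtraction, resampling, line-noise removal,
# demeaning, artifact masking.

test_that("spike-waveform subtraction removes an embedded template", {
  fs <- 2000
  set.seed(1)
  x <- stats::rnorm(fs * 5, 0, 1)
  wf <- 40 * sin(2 * pi * seq(0, 1, length.out = 8)) * exp(-2 * seq(0, 1, length.out = 8))
  spk <- c(1.0, 2.5, 3.75)
  y <- x
  for (s in round(spk * fs) + 1) y[s:(s + 7)] <- y[s:(s + 7)] + wf
  base <- lfp_trace(y, fs)
  # zero waveform: identity
  out0 <- subtract_spike_waveforms(base, list(spk), list(rep(0, 8)))
  expect_identical(out0$samples, y)
  out <- subtract_spike_waveforms(base, list(spk), list(wf))
  for (s in round(spk * fs) + 1) {
    resid <- out$samples[s:(s + 7)] - x[s:(s + 7)]
    expect_lt(max(abs(resid)), 0.05 * max(abs(wf)) + 1e-9)
  }
  # two units overlapping: additive, order independent
  out_ab <- subtract_spike_waveforms(base, list(spk, spk[2]), list(wf, wf / 2))
  out_ba <- subtract_spike_waveforms(base, list(spk[2], spk), list(wf / 2, wf))
  expect_equal(out_ab$samples, out_ba$samples, tolerance = 1e-12)
  expect_warning(subtract_spike_waveforms(base, list(99), list(wf)), "skipped")
})

test_that("resampling preserves sinusoids, durations and refuses upsampling", {
  fs <- 30000
  t <- seq(1 / fs, 1, by = 1 / fs)
  r <- resample_trace(lfp_trace(sin(2 * pi * 5 * t), fs), 2000)
  expect_equal(length(r$samples), 2000)
  expect_equal(r$fs, 2000)
  interior <- r$samples[400:1600]
  t2 <- seq(1 / 2000, 1, by = 1 / 2000)[400:1600]
  expect_lt(max(abs(interior - sin(2 * pi * 5 * t2))), 0.01)
  same <- resample_trace(lfp_trace(sin(2 * pi * 5 * t2), 2000), 2000)
  expect_identical(same$samples, sin(2 * pi * 5 * t2))
  expect_error(resample_trace(lfp_trace(1:10, 100), 200), "upsampling")
})

test_that("line-noise filter notches 50 Hz and leaves theta untouched", {
  fs <- 2000
  t <- seq(1 / fs, 10, by = 1 / fs)
  i <- 4000:16000 # away from edges
  out50 <- remove_line_noise(lfp_trace(sin(2 * pi * 50 * t), fs))
  expect_lt(stats::sd(out50$samples[i]) / stats::sd(sin(2 * pi * 50 * t)), 0.03)
  out5 <- remove_line_noise(lfp_trace(sin(2 * pi * 5 * t), fs))
  expect_lt(abs(stats::sd(out5$samples[i]) /
                  stats::sd(sin(2 * pi * 5 * t)[i]) - 1), 0.01)
  mix <- remove_line_noise(lfp_trace(sin(2 * pi * 5 * t) + sin(2 * pi * 50 * t), fs))
  pg <- thetalock:::periodogram_power(mix$samples[i], fs)
  p5 <- pg$power[which.min(abs(pg$freq - 5))]
  p50 <- pg$power[which.min(abs(pg$freq - 50))]
  expect_gt(10 * log10(p5 / p50), 30)
  expect_error(remove_line_noise(lfp_trace(stats::rnorm(1000), 300)), "320")
})

test_that("demeaning centres exactly and commutes with the line filter", {
  fs <- 2000
  x <- gen_pink_noise(fs * 4, fs, 1, seed = 5) + 100
  lfp <- lfp_trace(x, fs)
  expect_equal(mean(demean(lfp)$samples), 0, tolerance = 1e-12)
  expect_identical(demean(lfp_trace(rep(7, 100), fs))$samples, rep(0, 100))
  a <- demean(remove_line_noise(lfp))$samples
  b <- remove_line_noise(demean(lfp))$samples
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("IED detection flags injected transients, not clean pink noise", {
  fs <- 2000
  fracs <- vapply(1:3, function(s) {
    m <- detect_ieds(lfp_trace(gen_pink_noise(fs * 60, fs, 1, seed = s, sd = 30), fs))
    attr(m, "total_masked_s") / 60
  }, numeric(1))
  expect_lt(mean(fracs), 0.01)
  x <- gen_pink_noise(fs * 60, fs, 1, seed = 3, sd = 30)
  len <- round(0.25 * fs)
  s01 <- seq(0, 1, length.out = len)
  shape <- sin(2 * pi * s01) * exp(-4 * s01)
  shape <- 8 * 30 * shape / max(abs(shape))
  x[60000:(60000 + len - 1)] <- x[60000:(60000 + len - 1)] + shape
  m <- detect_ieds(lfp_trace(x, fs))
  peak_at <- 60000 + which.max(abs(shape)) - 1
  expect_true(any(m$start <= peak_at & m$end > peak_at))
  expect_error(detect_ieds(lfp_trace(stats::rnorm(500), fs)), "1 s")
})

test_that("artifact mask intervals are sorted, disjoint, and merging is stable", {
  flag <- rep(FALSE, 10000)
  flag[c(2000:2010, 2300:2310, 6000)] <- TRUE # first two merge via padding
  m <- thetalock:::mask_from_flags(flag, 2000, 0.25)
  expect_true(all(diff(m$start) > 0))
  expect_true(all(m$start[-1] > m$end[-nrow(m)]))
  # idempotent: flags derived from the mask give the mask back
  flag2 <- rep(FALSE, 10000)
  for (i in seq_len(nrow(m))) flag2[m$start[i]:(m$end[i] - 1)] <- TRUE
  m2 <- thetalock:::mask_from_flags(flag2, 2000, 0)
  expect_equal(m2$start, m$start)
  expect_equal(pmin(m2$end, 10001), pmin(m$end, 10001))
})
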