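# Generalized phase: bandpass behaviour, analytic phase, interpolation of
# sub-cutoff epochs, spike annotation.

test_that("theta bandpass passes 5 Hz, rejects 25 Hz and DC", {
  fs <- 2000
  t <- seq(1 / fs, 20, by = 1 / fs)
  i <- 10000:30000
  f5 <- bandpass_theta(lfp_trace(sin(2 * pi * 5 * t), fs))
  expect_lt(abs(max(f5$samples[i]) - 1), 0.02)
  f25 <- bandpass_theta(lfp_trace(sin(2 * pi * 25 * t), fs))
  expect_lt(20 * log10(max(abs(f25$samples[i]))), -20)
  fdc <- bandpass_theta(lfp_trace(rep(3, length(t)), fs))
  expect_lt(max(abs(fdc$samples[i])), 1e-6)
  expect_error(bandpass_theta(lfp_trace(stats::rnorm(1000), fs)), "3x")
})

test_that("phase of a pure sinusoid progresses at its frequency with unit power", {
  fx <- fix_sine_phase() # 4 Hz, amplitude 50
  ps <- fx$ps
  i <- 10000:30000
  up <- thetalock:::unwrap_phase(ps$phase[i])
  slope_hz <- (up[length(up)] - up[1]) / (length(i) / 2000) / (2 * pi)
  expect_lt(abs(slope_hz - 4) / 4, 0.01)
  expect_false(any(ps$interp_mask[i]))
  expect_lt(max(abs(ps$power[i] / 50^2 - 1)), 0.05)
  expect_true(all(ps$power == ps$magnitude^2))
  expect_error(generalized_phase(lfp_trace(rep(0, 1000), 2000)), "all-zero")
})

test_that("phase reversals from a high-frequency intrusion are interpolated away", {
  fs <- 2000
  t <- seq(1 / fs, 20, by = 1 / fs)
  x <- sin(2 * pi * 4 * t) + 0.35 * sin(2 * pi * 20 * t)
  ps <- generalized_phase(lfp_trace(x, fs)) # deliberately unfiltered input
  i <- 5000:35000
  expect_gt(sum(ps$interp_mask[i]), 0)
  up <- thetalock:::unwrap_phase(ps$phase[i])
  # reversals are gone after interpolation: phase progression is
  # non-decreasing up to centred-difference slack at epoch borders
  expect_gt(min(diff(up)), -0.05)
  expect_gt(mean(diff(up) >= 0), 0.999)
  slope_hz <- (up[length(up)] - up[1]) / (length(i) / 2000) / (2 * pi)
  expect_lt(abs(slope_hz - 4), 0.5)
  # untouched samples keep their analytic phase bitwise
  raw <- Arg(thetalock:::analytic_signal(x))
  expect_identical(ps$phase[i][!ps$interp_mask[i]], raw[i][!ps$interp_mask[i]])
})

test_that("troughs of the filtered trace sit at |phase| > 3", {
  fx <- fix_sine_phase()
  i <- 10000:30000
  x <- fx$filt$samples
  is_min <- which(diff(sign(diff(x))) > 0) + 1
  is_min <- is_min[is_min > min(i) & is_min < max(i)]
  expect_true(all(abs(fx$ps$phase[is_min]) > 3.0))
})

test_that("spike annotation uses nearest sample with ties to the earlier one", {
  ps <- structure(list(phase = c(0.1, 0.2, 0.3, 0.4), magnitude = rep(1, 4),
                       power = rep(1, 4), interp_mask = rep(FALSE, 4),
                       fs = 1000), class = "phase_series")
  tab <- assign_spikes(c(0.001, 0.0015, 0.0032), ps)
  expect_equal(tab$phase, c(0.2, 0.2, 0.4)) # exact midpoint -> earlier sample
  expect_message(assign_spikes(c(0.001, 1), ps), "dropped")
  mask <- tibble::tibble(start = 3L, end = 4L)
  class(mask) <- c("artifact_mask", class(mask))
  tab2 <- assign_spikes(c(0.001, 0.0021), ps, mask)
  expect_equal(nrow(tab2), 1) # spike at sample 3 removed by mask
})

test_that("power median split halves the spikes of a synthetic unit", {
  ann <- fix_small_session()$annotated
  st <- ann$spikes[ann$spikes$unit_id == "u1", ]
  lab <- median_split(st$log_power)
  expect_lte(abs(sum(lab == "high") - sum(lab == "low")), 1)
})

test_that("locked spikes recover their generating phase end to end", {
  ann <- fix_small_session()$annotated
  st <- ann$spikes[ann$spikes$unit_id == "u1", ] # kappa 4, mu pi
  expect_gt(nrow(st), 200)
  expect_angle_equal(circ_mean_r(st$phase)$mu, pi, 10 * pi / 180)
})
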