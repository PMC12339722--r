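# Time-resolved spectral parameterization.

gauss_peak <- function(f, ctr, hgt, wid) hgt * exp(-(f - ctr)^2 / (2 * wid^2))

test_that("frame geometry: 60 s of signal gives 115 3-s frames every 500 ms", {
  fs <- 2000
  fr <- timefreq_spectra(lfp_trace(gen_pink_noise(fs * 60, fs, 1, seed = 1), fs))
  expect_equal(length(fr$time), 115)
  expect_equal(fr$time[2] - fr$time[1], 0.5, tolerance = 1e-6)
  expect_equal(fr$freq, 1:40)
  expect_error(timefreq_spectra(lfp_trace(stats::rnorm(fs), fs)), "3 s")
})

test_that("frames overlapping artifacts are invalid; sinusoid peaks at its bin", {
  fs <- 2000
  t <- seq(1 / fs, 30, by = 1 / fs)
  mask <- tibble::tibble(start = 20000L, end = 21000L)
  fr <- timefreq_spectra(lfp_trace(sin(2 * pi * 6 * t), fs), mask)
  # frames span 3 s: those safely inside the masked window are invalid,
  # those safely outside stay valid
  overlapping <- fr$time > 10 - 1.4 & fr$time < 10.5 + 1.4
  expect_true(all(!fr$valid[overlapping]))
  clear <- fr$time < 10 - 1.6 | fr$time > 10.5 + 1.6
  expect_true(all(fr$valid[clear]))
  ok <- which(fr$valid)
  for (f in ok[c(1, length(ok))]) {
    expect_equal(fr$freq[which.max(fr$power[f, ])], 6)
  }
})

test_that("aperiodic fit recovers noiseless power laws exactly", {
  ap <- fit_aperiodic(1:40, 10^2 * (1:40)^-1.5)
  expect_equal(ap$offset, 2, tolerance = 1e-6)
  expect_equal(ap$exponent, 1.5, tolerance = 1e-6)
  expect_lt(ap$rmse, 1e-10)
  expect_error(fit_aperiodic(1:40, c(-1, rep(1, 39))), "positive")
})

test_that("aperiodic fit is robust to an additive spectral peak", {
  freq <- 1:40
  for (chi in c(0.5, 1.5)) {
    p <- 10^(1 - chi * log10(freq)) * 10^(0.8 * exp(-(freq - 5)^2 / (2 * 2^2)))
    ap <- fit_aperiodic(freq, p)
    expect_lt(abs(ap$exponent - chi), 0.15)
  }
})

test_that("aperiodic fit is scale-equivariant", {
  freq <- 1:40
  p <- 10^(0.5 - 1.2 * log10(freq)) * (1 + 0.3 * sin(freq))
  a1 <- fit_aperiodic(freq, p)
  a2 <- fit_aperiodic(freq, p * 10^3)
  expect_equal(a2$offset - a1$offset, 3, tolerance = 1e-9)
  expect_equal(a2$exponent, a1$exponent, tolerance = 1e-9)
})

test_that("peak extraction finds injected Gaussians and prunes edge peaks", {
  freq <- 1:40
  ap <- list(offset = 1, exponent = 1)
  base <- 10^(1 - log10(freq))
  flat0 <- fit_peaks(freq, base, ap)
  expect_equal(nrow(flat0), 0)
  with_peak <- base * 10^gauss_peak(freq, 5, 1.0, 3)
  pk <- fit_peaks(freq, with_peak, ap)
  expect_equal(nrow(pk), 1)
  expect_lt(abs(pk$center - 5), 0.5)
  edge <- base * 10^gauss_peak(freq, 2, 1.0, 3)
  pk_edge <- fit_peaks(freq, edge, ap)
  expect_false(any(abs(pk_edge$center - 2) < 0.5))
})

test_that("exponent recovery from pink-noise traces is within 0.15", {
  fs <- 2000
  for (chi in c(0.5, 2)) {
    est <- vapply(1:5, function(s) {
      x <- gen_pink_noise(fs * 60, fs, chi, seed = 7000 + 10 * chi + s)
      fr <- fit_frames(timefreq_spectra(lfp_trace(x, fs)))
      mean(fr$exponent, na.rm = TRUE)
    }, numeric(1))
    expect_lt(abs(mean(est) - chi), 0.15)
  }
})

test_that("spikes inherit the slope of their 500 ms frame step", {
  ff <- tibble::tibble(frame = 1:5, time = c(1.5, 2, 2.5, 3, 3.5),
                       offset = 0, exponent = c(1, 2, 3, 4, 5),
                       rmse = 0, valid = c(TRUE, TRUE, FALSE, TRUE, TRUE))
  st <- tibble::tibble(time = c(1.5, 2.1, 2.6, 0.2, 9))
  out <- assign_spike_slopes(st, ff)
  expect_equal(out$slope_exponent, c(1, 2, NA, NA, NA))
})

test_that("slope-frequency correlation detects constructed dependence, is rank-invariant", {
  set.seed(5)
  mk <- function() {
    slope <- stats::runif(40, 0.5, 2)
    freq <- 8 - 2 * slope + stats::rnorm(40, 0, 0.3) # steeper -> slower
    ff <- tibble::tibble(frame = 1:40, time = seq(1.5, by = 0.5, length.out = 40),
                         offset = 0, exponent = slope, rmse = 0, valid = TRUE)
    cyc <- tibble::tibble(peak = round(ff$time * 2000), period = 1 / freq)
    slope_frequency_by_wire(ff, cyc, 2000)
  }
  tabs <- replicate(4, mk(), simplify = FALSE)
  res <- slope_frequency_correlation(tabs)
  expect_lt(mean(res$per_session), -0.3)
  expect_lt(res$p, 0.05)
  # rank invariance: monotone transform of slopes leaves rho unchanged
  ff <- tibble::tibble(frame = 1:30, time = seq(1.5, by = 0.5, length.out = 30),
                       offset = 0, exponent = stats::runif(30, 0.5, 2),
                       rmse = 0, valid = TRUE)
  cyc <- tibble::tibble(peak = round(ff$time * 2000),
                        period = 1 / stats::runif(30, 2, 9))
  r1 <- slope_frequency_by_wire(ff, cyc, 2000)$rho
  ff$exponent <- exp(3 * ff$exponent)
  r2 <- slope_frequency_by_wire(ff, cyc, 2000)$rho
  expect_equal(r1, r2, tolerance = 1e-12)
  expect_error(slope_frequency_correlation(tabs[1]), ">= 2 sessions")
})

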