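# Shared fixtures, built once per test run and memoised.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# a clean 5 Hz sinusoid trace at 2 kHz
fix_sinusoid <- function(freq = 5, dur = 20, fs = 2000, amp = 1) {
  t <- seq(1 / fs, dur, by = 1 / fs)
  lfp_trace(amp * sin(2 * pi * freq * t), fs)
}

# filtered trace + phase series for a 4 Hz sinusoid
fix_sine_phase <- function() {
  memo("sine_phase", function() {
    f <- bandpass_theta(fix_sinusoid(4, 20, 2000, 50))
    list(filt = f, ps = generalized_phase(f))
  })
}

# a small fully annotated locked-unit session
fix_small_session <- function() {
  memo("small_session", function() {
    cfg <- synth_config(units = list(
      unit_spec(mode = "locked", kappa = 4, base_rate = 2),
      unit_spec(mode = "poisson", base_rate = 2)
    ), n_trials = 8, seed = 301)
    ses <- gen_session(cfg)
    list(session = ses,
         annotated = annotate_session(ses, fit_slopes = FALSE,
                                      n_potential = 5e3))
  })
}

# uniform-ramp phase series for spike-generation statistics (theta at 4 Hz)
fix_ramp_phase <- function(dur = 500, fs = 200, freq = 4) {
  wrap <- function(x) (x + pi) %% (2 * pi) - pi
  wrap(2 * pi * freq * seq(1 / fs, dur, by = 1 / fs))
}

expect_angle_equal <- function(a, b, tol) {
  d <- atan2(sin(a - b), cos(a - b))
  expect_lt(abs(d), tol)
}
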