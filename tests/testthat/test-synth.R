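# Synthetic-session generator: spectral slopes, burst geometry, spike
# statistics and determinism.

test_that("pink noise hits its target spectral exponent", {
  white <- gen_pink_noise(2^16, 2000, 0, seed = 1)
  expect_lt(abs(thetalock:::loglog_slope(white, 2000)), 0.1)
  pink <- gen_pink_noise(2^18, 2000, 1, seed = 2)
  sl <- thetalock:::loglog_slope(pink, 2000)
  expect_true(sl > -1.15 && sl < -0.85)
  expect_identical(gen_pink_noise(4096, 2000, 1, seed = 7),
                   gen_pink_noise(4096, 2000, 1, seed = 7))
  expect_error(gen_pink_noise(0, 2000, 1), "positive")
})

test_that("burst geometry: cycle count fixes duration; zero rate is silent", {
  z <- gen_theta_bursts(60, 2000, c(3, 5), 0, c(4, 8), amplitude = 1, seed = 1)
  expect_true(all(z$trace == 0))
  expect_equal(nrow(z$bursts), 0)
  # force a single 4 Hz, 8-cycle burst by narrow ranges and no drift
  b <- NULL
  for (s in 1:50) {
    cand <- gen_theta_bursts(30, 2000, c(4, 4 + 1e-9), 2, c(8, 8),
                             amplitude = 1, seed = s, drift_sd = 0)
    if (nrow(cand$bursts) == 1) { b <- cand; break }
  }
  expect_equal(b$bursts$n_cycles, 8)
  expect_equal(b$bursts$offset - b$bursts$onset + 1, 8 / 4 * 2000)
  expect_error(gen_theta_bursts(60, 2000, c(3, 5), 5, c(1, 8), amplitude = 1),
               ">= 2")
})

test_that("burst count is near the nominal rate and bursts never overlap", {
  counts <- vapply(1:30, function(s) {
    nrow(gen_theta_bursts(600, 2000, c(3, 5), 6, c(4, 8), amplitude = 1,
                          seed = s)$bursts)
  }, numeric(1))
  expect_gt(mean(counts), 60 * 0.5)
  expect_lt(mean(counts), 60 * 1.5)
  b <- gen_theta_bursts(600, 2000, c(3, 5), 20, c(4, 12), amplitude = 1,
                        seed = 3)$bursts
  expect_true(all(b$onset[-1] > b$offset[-nrow(b)]))
})

test_that("phase-locked spiking: kappa 0 is Poisson, kappa > 0 concentrates", {
  ph <- fix_ramp_phase(600, 200)
  st0 <- gen_spikes_phase_locked(ph, 200, base_rate = 2, kappa = 0, mu = 0,
                                 seed = 5)
  expect_lt(abs(length(st0) - 1200), 3 * sqrt(1200))
  ph_at <- function(st) ph[pmin(length(ph), round(st * 200) + 1)]
  expect_gt(rayleigh(ph_at(st0))$p, 0.001) # no spurious locking
  st4 <- gen_spikes_phase_locked(ph, 200, base_rate = 2, kappa = 4, mu = pi,
                                 seed = 6)
  expect_gt(length(st4), 500)
  expect_angle_equal(circ_mean_r(ph_at(st4))$mu, pi, 10 * pi / 180)
  expect_error(gen_spikes_phase_locked(numeric(0), 200, 2, 1, 0), "empty")
})

test_that("measured PPC increases strictly with kappa", {
  ph <- fix_ramp_phase(500, 200)
  ph_at <- function(st) ph[pmin(length(ph), round(st * 200) + 1)]
  kappas <- c(0, 0.5, 1, 2, 4)
  mean_ppc <- vapply(kappas, function(k) {
    mean(vapply(1:20, function(s) {
      st <- gen_spikes_phase_locked(ph, 200, base_rate = 2, kappa = k,
                                    mu = 0.5, seed = 1000 * k + s)
      ppc(ph_at(st))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_ppc) > 0))
})

test_that("resonant trains are periodic and rate-matched", {
  st <- gen_spikes_resonant(60, 4, 4, jitter_sd = 0, seed = 1)
  expect_equal(length(st), 240)
  expect_true(all(abs(diff(st) - 0.25) < 1e-9))
  st2 <- gen_spikes_resonant(600, 2, 4, jitter_sd = 0.01, seed = 2)
  expect_lt(abs(length(st2) - 1200), 4 * sqrt(1200))
  expect_error(gen_spikes_resonant(60, 2, 12), "resonance_freq")
  expect_error(gen_spikes_resonant(60, 2, 4, jitter_sd = -1), "jitter")
})

test_that("sessions are reproducible bit for bit from the seed", {
  cfg <- synth_config(units = list(unit_spec(base_rate = 1.5)), n_trials = 3,
                      seed = 99)
  s1 <- gen_session(cfg)
  s2 <- gen_session(cfg)
  expect_identical(s1$lfp[[1]]$samples, s2$lfp[[1]]$samples)
  expect_identical(s1$units$spikes, s2$units$spikes)
  expect_identical(s1$behavior, s2$behavior)
  expect_error(synth_config(n_trials = 1), "n_trials")
})

test_that("session structure: trials, distractor, alternating recall kinds", {
  ses <- fix_small_session()$session
  seg <- ses$segments
  expect_true(all(table(seg$trial[seg$type == "encoding"]) %in% 2:3))
  expect_equal(unique(round(seg$end_s - seg$start_s)[seg$type == "distractor"]), 7)
  kinds <- unique(seg[seg$type %in% c("recall_object", "recall_location"),
                      c("trial", "type")])
  expect_true(all(kinds$type[kinds$trial %% 2 == 1] == "recall_object"))
  expect_true(all(kinds$type[kinds$trial %% 2 == 0] == "recall_location"))
})
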