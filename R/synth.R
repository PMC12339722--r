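# Synthetic-session generator. Emulates the structure of human microwire
# recordings during an object-location memory task: pink-noise LFP with
# transient theta bursts of drifting frequency, 50 Hz line noise, optional
# epileptiform-like transients, spike trains that are von-Mises phase-locked
# (with condition-dependent preferred phases), Poisson, or theta-resonant but
# field-independent, and a trial structure with improving memory performance.
# Ground truth for every generated quantity is returned so each downstream
# stage has a parameter-recovery test.

#' Pink noise via spectral synthesis
#'
#' Draws random Fourier phases and shapes amplitudes as f^(-exponent/2), so
#' the periodogram slope in log-log space over 1-40 Hz is -exponent by
#' construction. The trace is zero-mean and scaled to unit SD (multiply by
#' `sd` for other scales).
#'
#' @param n_samples Number of samples (> 0).
#' @param fs Sampling rate, Hz.
#' @param exponent Spectral exponent chi >= 0 (power ~ f^-chi); 0 gives
#'   white noise.
#' @param seed Integer seed; identical seeds give identical traces.
#' @param sd Target standard deviation (default 1).
#' @return Numeric vector of length `n_samples`.
#' @export
gen_pink_noise <- function(n_samples, fs, exponent = 1, seed = 1, sd = 1) {
  if (n_samples <= 0) stop("`n_samples` must be positive", call. = FALSE)
  if (exponent < 0) stop("`exponent` must be >= 0", call. = FALSE)
  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  n <- n_samples
  nf <- floor(n / 2)
  freqs <- (1:nf) * fs / n
  amp <- freqs^(-exponent / 2)
  ph <- stats::runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = ph)
  full <- complex(real = numeric(n))
  full[2:(nf + 1)] <- spec
  if (n %% 2 == 0) {
    full[nf + 1] <- complex(real = amp[nf] * cos(ph[nf])) # Nyquist must be real
    full[seq(n, nf + 2)] <- Conj(spec[1:(nf - 1)])
  } else {
    full[seq(n, nf + 1)] <- Conj(spec)
  }
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  x <- x - mean(x)
  x / stats::sd(x) * sd
}

#' Transient theta bursts
#'
#' Adds non-overlapping oscillatory bursts to an otherwise silent trace.
#' Each burst is a sinusoid with frequency drawn uniformly from
#' `freq_range`, an integer cycle count from `cycles_range`, optional linear
#' frequency drift (bounded to stay within [1, 10] Hz), and cosine (Hann)
#' on/off ramps of one cycle at each end. Burst placement is
#' rejection-resampled so bursts never overlap; the returned burst table
#' records exact onset/offset samples and frequency.
#'
#' @param duration_s Trace duration, seconds.
#' @param fs Sampling rate, Hz.
#' @param freq_range Length-2 Hz range within [1, 10].
#' @param burst_rate Expected bursts per minute.
#' @param cycles_range Length-2 integer range of cycles per burst (min >= 2).
#' @param amplitude Peak amplitude of each burst (same units as the LFP).
#' @param seed Integer seed.
#' @param drift_sd SD of the per-burst linear frequency drift (Hz over the
#'   burst); 0 disables drift.
#' @return A list with `trace` (numeric), `bursts` (tibble: onset, offset,
#'   freq, freq_end, n_cycles) and `phase` (instantaneous burst phase per
#'   sample, NA outside bursts).
#' @export
gen_theta_bursts <- function(duration_s, fs, freq_range = c(3, 5),
                             burst_rate = 10, cycles_range = c(4, 12),
                             amplitude = 1, seed = 1, drift_sd = 0.5) {
  stopifnot(duration_s > 0, fs >= 1000, amplitude > 0, burst_rate >= 0)
  if (freq_range[1] < 1 || freq_range[2] > 10 || freq_range[1] > freq_range[2]) {
    stop("`freq_range` must lie within [1, 10] Hz", call. = FALSE)
  }
  if (cycles_range[1] < 2) {
    stop("`cycles_range` minimum must be >= 2 (bouts require >= 2 cycles)",
         call. = FALSE)
  }
  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  n <- round(duration_s * fs)
  trace <- numeric(n)
  phase <- rep(NA_real_, n)
  n_bursts <- stats::rpois(1, burst_rate * duration_s / 60)
  rows <- list()
  occupied <- logical(n)
  for (b in seq_len(n_bursts)) {
    placed <- FALSE
    for (try in 1:200) {
      f0 <- stats::runif(1, freq_range[1], freq_range[2])
      cyc_opts <- seq(cycles_range[1], cycles_range[2])
      ncyc <- cyc_opts[sample.int(length(cyc_opts), 1)]
      f1 <- f0 + stats::rnorm(1, 0, drift_sd)
      f1 <- min(10, max(1, f1))
      dur <- ncyc / mean(c(f0, f1))
      len <- round(dur * fs)
      if (len >= n) next
      onset <- sample.int(n - len, 1)
      idx <- onset:(onset + len - 1)
      if (any(occupied[idx])) next
      finst <- seq(f0, f1, length.out = len)
      ph <- cumsum(2 * pi * finst / fs)
      ramp <- min(len %/% 2, round(fs / mean(c(f0, f1)))) # one cycle
      env <- rep(1, len)
      if (ramp > 0) {
        r <- 0.5 - 0.5 * cos(pi * seq_len(ramp) / ramp)
        env[1:ramp] <- r
        env[(len - ramp + 1):len] <- rev(r)
      }
      trace[idx] <- amplitude * env * cos(ph)
      phase[idx] <- wrap_pi(ph)
      occupied[idx] <- TRUE
      rows[[length(rows) + 1]] <- tibble::tibble(
        onset = onset, offset = onset + len - 1L,
        freq = f0, freq_end = f1, n_cycles = ncyc
      )
      placed <- TRUE
      break
    }
    if (!placed) next # trace saturated; fewer bursts than nominal
  }
  bursts <- if (length(rows)) {
    dplyr::arrange(dplyr::bind_rows(rows), .data$onset)
  } else {
    tibble::tibble(onset = integer(), offset = integer(), freq = numeric(),
                   freq_end = numeric(), n_cycles = integer())
  }
  list(trace = trace, bursts = bursts, phase = phase)
}

# von Mises density (unnormalised by 2*pi handled by caller)
vm_density <- function(theta, mu, kappa) {
  exp(kappa * cos(theta - mu)) / (2 * pi * besselI(kappa, 0, expon.scaled = FALSE))
}

#' Phase-locked spike train via von Mises intensity thinning
#'
#' Generates an inhomogeneous Poisson spike train with intensity
#' lambda(t) = base_rate * 2 pi * vonMises(theta(t); mu, kappa). The 2 pi
#' normalisation keeps the mean rate near `base_rate` under uniform phase
#' occupancy, and kappa = 0 reduces exactly to a homogeneous Poisson train.
#' With `lock_only_in_bursts`, modulation applies inside the supplied burst
#' intervals only and the rate is `base_rate` elsewhere.
#'
#' @param phase Per-sample phase (radians) the unit locks to; NA samples are
#'   treated as unmodulated.
#' @param fs Sampling rate of `phase`, Hz.
#' @param base_rate Mean firing rate, Hz (> 0).
#' @param kappa von Mises concentration (>= 0).
#' @param mu Preferred phase, radians; either a scalar or a per-sample vector
#'   (for condition-dependent preferred phases).
#' @param lock_only_in_bursts If TRUE, modulate only within `bursts` rows.
#' @param bursts Burst table with `onset`/`offset` sample columns.
#' @param seed Integer seed.
#' @return Numeric vector of spike times in seconds, sorted.
#' @export
gen_spikes_phase_locked <- function(phase, fs, base_rate, kappa, mu,
                                    lock_only_in_bursts = FALSE, bursts = NULL,
                                    seed = 1) {
  if (length(phase) == 0) stop("empty phase series", call. = FALSE)
  if (kappa < 0) stop("`kappa` must be >= 0", call. = FALSE)
  stopifnot(base_rate > 0)
  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  dur <- length(phase) / fs
  lambda_max <- base_rate * exp(kappa) / besselI(kappa, 0)
  n_cand <- stats::rpois(1, lambda_max * dur)
  cand <- sort(stats::runif(n_cand, 0, dur))
  samp <- pmin(length(phase), pmax(1L, round(cand * fs) + 1L))
  modulated <- rep(TRUE, length(cand))
  if (lock_only_in_bursts) {
    if (is.null(bursts)) stop("`bursts` required when lock_only_in_bursts", call. = FALSE)
    modulated <- in_intervals(samp, bursts$onset, bursts$offset)
  }
  th <- phase[samp]
  modulated <- modulated & !is.na(th)
  mu_s <- if (length(mu) == length(phase)) mu[samp] else rep(mu[1], length(cand))
  lambda <- rep(base_rate, length(cand))
  lambda[modulated] <- base_rate * 2 * pi *
    vm_density(th[modulated], mu_s[modulated], kappa)
  keep <- stats::runif(length(cand)) < lambda / lambda_max
  cand[keep]
}

#' Theta-resonant, field-independent spike train
#'
#' Spikes at multiples of 1/resonance_freq with Gaussian jitter and random
#' dropout to hit the target rate. The train is statistically independent of
#' any LFP: its rhythmicity alone should not produce spike-field locking.
#'
#' @param duration_s Duration, seconds.
#' @param rate Target firing rate, Hz (<= resonance_freq for dropout; higher
#'   rates keep every beat).
#' @param resonance_freq Intrinsic rhythm frequency in [1, 10] Hz.
#' @param jitter_sd Gaussian timing jitter SD, seconds (>= 0).
#' @param seed Integer seed.
#' @return Numeric vector of spike times in seconds, sorted.
#' @export
gen_spikes_resonant <- function(duration_s, rate, resonance_freq,
                                jitter_sd = 0.01, seed = 1) {
  if (resonance_freq < 1 || resonance_freq > 10) {
    stop("`resonance_freq` must be in [1, 10] Hz", call. = FALSE)
  }
  if (jitter_sd < 0) stop("`jitter_sd` must be >= 0", call. = FALSE)
  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  beats <- seq(1 / resonance_freq, duration_s, by = 1 / resonance_freq)
  keep_p <- min(1, rate / resonance_freq)
  beats <- beats[stats::runif(length(beats)) < keep_p]
  t <- beats + if (jitter_sd > 0) stats::rnorm(length(beats), 0, jitter_sd) else 0
  sort(t[t > 0 & t <= duration_s])
}

# half-open-on-right membership check against sorted interval columns
in_intervals <- function(idx, starts, ends) {
  if (length(starts) == 0) return(rep(FALSE, length(idx)))
  out <- rep(FALSE, length(idx))
  for (k in seq_along(starts)) {
    out <- out | (idx >= starts[k] & idx <= ends[k])
  }
  out
}

#' Synthetic-session configuration
#'
#' Bundles all generator parameters. Defaults reflect the signal regimes the
#' pipeline targets: 1/f LFP background (exponent 1), theta bursts most often
#' at 3-5 Hz, and trials whose memory performance improves over the session.
#'
#' @param duration_s Session duration, seconds; if NULL, derived from the
#'   trial structure.
#' @param fs Sampling rate, Hz (>= 1000).
#' @param pink_exponent Aperiodic spectral exponent chi.
#' @param noise_sd LFP background SD, microvolts.
#' @param line_noise_amp 50 Hz line-noise amplitude, microvolts.
#' @param line_harmonics Add 100/150 Hz harmonics at half/third amplitude.
#' @param burst_rate Theta bursts per minute.
#' @param burst_freq_range Hz pair within [1, 10].
#' @param burst_cycles_range Integer pair, cycles per burst (min >= 2).
#' @param burst_snr Burst amplitude as a multiple of `noise_sd`.
#' @param ied_rate Epileptiform-like transients per minute.
#' @param units List of [unit_spec()] entries.
#' @param n_trials Number of trials (>= 2).
#' @param success_range Start/end success probability over the session.
#' @param arena Length-2 rectangle side lengths, virtual units.
#' @param seed Master integer seed; all sub-generators derive from it.
#' @return A `synth_config` list.
#' @export
synth_config <- function(duration_s = NULL, fs = 2000, pink_exponent = 1,
                         noise_sd = 30, line_noise_amp = 10,
                         line_harmonics = TRUE, burst_rate = 10,
                         burst_freq_range = c(3, 5),
                         burst_cycles_range = c(4, 12), burst_snr = 2,
                         ied_rate = 0, units = list(unit_spec()),
                         n_trials = 20, success_range = c(0.4, 0.8),
                         arena = c(100, 100), seed = 1) {
  stopifnot(fs >= 1000, burst_rate >= 0, ied_rate >= 0)
  if (n_trials < 2) stop("`n_trials` must be >= 2", call. = FALSE)
  cfg <- list(duration_s = duration_s, fs = fs, pink_exponent = pink_exponent,
              noise_sd = noise_sd, line_noise_amp = line_noise_amp,
              line_harmonics = line_harmonics, burst_rate = burst_rate,
              burst_freq_range = burst_freq_range,
              burst_cycles_range = burst_cycles_range, burst_snr = burst_snr,
              ied_rate = ied_rate, units = units, n_trials = n_trials,
              success_range = success_range, arena = arena, seed = seed)
  structure(cfg, class = "synth_config")
}

#' Synthetic unit specification
#'
#' @param mode "locked" (von Mises phase-locked), "poisson", or "resonant"
#'   (rhythmic but field-independent).
#' @param base_rate Mean firing rate, Hz.
#' @param kappa von Mises concentration (locked mode).
#' @param mu_encoding,mu_retrieval Preferred phases (radians in (-pi, pi])
#'   during encoding and recall segments; elsewhere `mu_encoding` applies.
#' @param lock_only_in_bursts Restrict modulation to theta bursts.
#' @param resonance_freq Hz (resonant mode).
#' @param wire Wire index the unit sits on.
#' @param waveform_amp Peak spike-waveform amplitude added to the LFP,
#'   microvolts.
#' @return A `unit_spec` list.
#' @export
unit_spec <- function(mode = c("locked", "poisson", "resonant"),
                      base_rate = 2, kappa = 4, mu_encoding = pi,
                      mu_retrieval = pi, lock_only_in_bursts = FALSE,
                      resonance_freq = 4, wire = 1, waveform_amp = 40) {
  mode <- match.arg(mode)
  stopifnot(base_rate > 0, kappa >= 0)
  if (abs(mu_encoding) > pi || abs(mu_retrieval) > pi) {
    stop("preferred phases must lie in (-pi, pi]", call. = FALSE)
  }
  structure(list(mode = mode, base_rate = base_rate, kappa = kappa,
                 mu_encoding = mu_encoding, mu_retrieval = mu_retrieval,
                 lock_only_in_bursts = lock_only_in_bursts,
                 resonance_freq = resonance_freq, wire = wire,
                 waveform_amp = waveform_amp),
            class = "unit_spec")
}

# biphasic spike template at the LFP rate; < 5 ms long
spike_template <- function(fs, amp) {
  n <- max(4L, round(0.004 * fs))
  t <- seq(0, 1, length.out = n)
  w <- amp * sin(2 * pi * t) * exp(-3 * t)
  w - mean(w) * 0 # keep raw; subtraction path handles mean removal
}

#' Generate a full synthetic session
#'
#' Builds the trial structure (2-3 encoding events per trial, a ~6.6 s
#' distractor, then object- or location-recall segments alternating by
#' trial), per-wire LFP (pink noise + theta bursts + line noise + optional
#' epileptiform transients), behavior with linearly improving success
#' probability, and per-unit spike trains embedded into the LFP through a
#' spike-waveform template. Locked units are modulated by the generalized
#' phase of the clean (pre-spike, pre-line-noise) LFP, so preferred-phase
#' recovery through the analysis pipeline is a genuine round trip.
#'
#' @param config A [synth_config()].
#' @return A `synth_session` list: `lfp` (list of [lfp_trace()]), `units`
#'   (tibble with list-columns `spikes` and `waveform`), `segments`,
#'   `behavior`, `ground_truth`, `config`.
#' @export
gen_session <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  set.seed(config$seed)
  subseed <- function() sample.int(.Machine$integer.max - 1L, 1)

  seg <- build_segments(config$n_trials, seed = subseed())
  needed <- max(seg$end_s) + 5
  dur <- if (is.null(config$duration_s)) needed else max(config$duration_s, needed)
  n <- round(dur * config$fs)
  fs <- config$fs

  behavior <- build_behavior(seg, config$success_range, config$arena,
                             seed = subseed())

  wires <- sort(unique(vapply(config$units, `[[`, numeric(1), "wire")))
  if (length(wires) == 0) wires <- 1
  lfp <- list(); gt_bursts <- list(); gt_ieds <- list()
  clean_phase <- list(); burst_tabs <- list()
  for (w in wires) {
    pink <- gen_pink_noise(n, fs, config$pink_exponent, seed = subseed(),
                           sd = config$noise_sd)
    bl <- gen_theta_bursts(dur, fs, config$burst_freq_range,
                           config$burst_rate, config$burst_cycles_range,
                           amplitude = config$burst_snr * config$noise_sd,
                           seed = subseed())
    clean <- pink + bl$trace[seq_len(n)]
    # phase modulator for locked units: analytic phase of the clean LFP
    filt <- bandpass_theta_vector(clean, fs)
    clean_phase[[as.character(w)]] <- Arg(analytic_signal(filt))
    burst_tabs[[as.character(w)]] <- bl
    x <- clean
    if (config$line_noise_amp > 0) {
      tt <- seq_len(n) / fs
      x <- x + config$line_noise_amp * sin(2 * pi * 50 * tt)
      if (config$line_harmonics) {
        x <- x + config$line_noise_amp / 2 * sin(2 * pi * 100 * tt) +
          config$line_noise_amp / 3 * sin(2 * pi * 150 * tt)
      }
    }
    ied_tab <- tibble::tibble(onset = integer(), offset = integer())
    if (config$ied_rate > 0) {
      set.seed(subseed())
      n_ied <- stats::rpois(1, config$ied_rate * dur / 60)
      if (n_ied > 0) {
        len <- round(0.25 * fs)
        onsets <- sort(sample.int(n - len, n_ied))
        s01 <- seq(0, 1, length.out = len)
        shape <- sin(2 * pi * s01) * exp(-4 * s01)
        shape <- 8 * config$noise_sd * shape / max(abs(shape)) # peak = 8 SD
        for (o in onsets) x[o:(o + len - 1)] <- x[o:(o + len - 1)] + shape
        ied_tab <- tibble::tibble(onset = onsets, offset = onsets + len - 1L)
      }
    }
    lfp[[as.character(w)]] <- lfp_trace(x, fs, wire_id = paste0("w", w),
                                        region = "synthetic")
    gt_bursts[[as.character(w)]] <- bl$bursts
    gt_ieds[[as.character(w)]] <- ied_tab
  }

  # per-sample preferred-phase vector from the segment taxonomy
  seg_type_of_sample <- segment_type_per_sample(seg, n, fs)

  unit_rows <- list()
  for (u in seq_along(config$units)) {
    us <- config$units[[u]]
    wkey <- as.character(us$wire)
    phase_w <- clean_phase[[wkey]]
    sd_seed <- subseed()
    spikes <- switch(us$mode,
      locked = {
        mu_vec <- ifelse(seg_type_of_sample == "recall",
                         us$mu_retrieval, us$mu_encoding)
        gen_spikes_phase_locked(phase_w, fs, us$base_rate, us$kappa, mu_vec,
                                lock_only_in_bursts = us$lock_only_in_bursts,
                                bursts = burst_tabs[[wkey]]$bursts,
                                seed = sd_seed)
      },
      poisson = gen_spikes_phase_locked(phase_w, fs, us$base_rate, 0, 0,
                                        seed = sd_seed),
      resonant = gen_spikes_resonant(dur, us$base_rate, us$resonance_freq,
                                     seed = sd_seed)
    )
    wf <- spike_template(fs, us$waveform_amp)
    samp <- round(spikes * fs) + 1L
    tr <- lfp[[wkey]]$samples
    for (s in samp) {
      j <- s:min(length(tr), s + length(wf) - 1L)
      tr[j] <- tr[j] + wf[seq_along(j)]
    }
    lfp[[wkey]]$samples <- tr
    unit_rows[[u]] <- tibble::tibble(
      unit_id = paste0("u", u), wire_id = paste0("w", us$wire),
      mode = us$mode, base_rate = us$base_rate, kappa = us$kappa,
      mu_encoding = us$mu_encoding, mu_retrieval = us$mu_retrieval,
      spikes = list(spikes), waveform = list(wf)
    )
  }

  structure(list(
    lfp = lfp,
    units = dplyr::bind_rows(unit_rows),
    segments = seg,
    behavior = behavior,
    ground_truth = list(bursts = gt_bursts, ieds = gt_ieds,
                        units = config$units),
    config = config
  ), class = "synth_session")
}

# Trial scaffold: per trial 2-3 encoding events (2 s, 1 s gaps), 6.6 s
# distractor, one 5 s recall (object/location alternating), 2 s inter-trial.
build_segments <- function(n_trials, seed) {
  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  rows <- list()
  t <- 2
  for (tr in seq_len(n_trials)) {
    n_enc <- sample(2:3, 1)
    for (e in seq_len(n_enc)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        type = "encoding", start_s = t, end_s = t + 2, trial = tr,
        event = e)
      t <- t + 3
    }
    rows[[length(rows) + 1]] <- tibble::tibble(
      type = "distractor", start_s = t, end_s = t + 6.6, trial = tr,
      event = NA_integer_)
    t <- t + 7.6
    kind <- if (tr %% 2 == 1) "recall_object" else "recall_location"
    for (e in seq_len(n_enc)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        type = kind, start_s = t, end_s = t + 5, trial = tr, event = e)
      t <- t + 6
    }
    t <- t + 2
  }
  seg <- dplyr::bind_rows(rows)
  seg$segment_id <- seq_len(nrow(seg))
  seg
}

build_behavior <- function(seg, success_range, arena, seed) {
  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  rec <- dplyr::filter(seg, .data$type %in% c("recall_object", "recall_location"))
  n_trials <- max(seg$trial)
  p_of <- function(tr) {
    if (n_trials == 1) return(mean(success_range))
    success_range[1] + (success_range[2] - success_range[1]) *
      (tr - 1) / (n_trials - 1)
  }
  purrr::pmap_dfr(rec, function(type, start_s, end_s, trial, event, segment_id) {
    p <- p_of(trial)
    if (type == "recall_object") {
      tibble::tibble(segment_id = segment_id, trial = trial,
                     kind = "object", correct = stats::runif(1) < p,
                     drop_error = NA_real_,
                     true_x = NA_real_, true_y = NA_real_,
                     response_time = stats::runif(1, 1, 4))
    } else {
      true_x <- stats::runif(1, 0, arena[1])
      true_y <- stats::runif(1, 0, arena[2])
      accurate <- stats::runif(1) < p
      de <- if (accurate) {
        # Rayleigh-distributed small error
        (min(arena) / 12) * sqrt(-2 * log(stats::runif(1)))
      } else {
        rx <- stats::runif(1, 0, arena[1]); ry <- stats::runif(1, 0, arena[2])
        sqrt((rx - true_x)^2 + (ry - true_y)^2)
      }
      tibble::tibble(segment_id = segment_id, trial = trial,
                     kind = "location", correct = NA,
                     drop_error = de, true_x = true_x, true_y = true_y,
                     response_time = stats::runif(1, 1, 6))
    }
  })
}

segment_type_per_sample <- function(seg, n, fs) {
  out <- rep("baseline", n)
  for (i in seq_len(nrow(seg))) {
    a <- max(1L, floor(seg$start_s[i] * fs) + 1L)
    b <- min(n, ceiling(seg$end_s[i] * fs))
    if (a > b) next
    out[a:b] <- switch(seg$type[i],
                       encoding = "encoding",
                       recall_object = "recall",
                       recall_location = "recall",
                       "baseline")
  }
  out
}

#' @export
print.synth_session <- function(x, ...) {
  cat(sprintf("<synth_session> %d wire(s), %d unit(s), %d segments, %.0f s @ %g Hz\n",
              length(x$lfp), nrow(x$units), nrow(x$segments),
              duration_s(x$lfp[[1]]), x$lfp[[1]]$fs))
  invisible(x)
}
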