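# Unit QC and inclusion, per-spike condition labelling, orchestration of the
# locking and contrast analyses, encoding-versus-retrieval phase-shift
# testing, and the empirical chance-level control.

#' Classify a unit as single- or multi-unit
#'
#' Single units require a waveform peak SNR (peak of the mean waveform over
#' the SD across spikes at the first waveform sample) greater than 3 and
#' fewer than 1% of inter-spike intervals shorter than 3 ms. Everything else
#' is a multi-unit. (Visual cluster-quality criteria are out of band and
#' not evaluated here.)
#'
#' @param waveforms Spikes x samples matrix of individual waveforms.
#' @param spike_times Spike times, seconds.
#' @return A one-row tibble: `snr`, `isi_violation_pct`, `class`.
#' @export
classify_unit <- function(waveforms, spike_times) {
  if (length(spike_times) < 2) {
    return(tibble::tibble(snr = NA_real_, isi_violation_pct = NA_real_,
                          class = "multi"))
  }
  mw <- colMeans(waveforms)
  noise_sd <- stats::sd(waveforms[, 1])
  snr <- max(abs(mw)) / noise_sd
  isi <- diff(sort(spike_times))
  isi_pct <- 100 * mean(isi < 0.003)
  tibble::tibble(snr = snr, isi_violation_pct = isi_pct,
                 class = if (snr > 3 && isi_pct < 1) "single" else "multi")
}

#' Unit inclusion by condition spike counts
#'
#' A unit is retained iff it has at least 25 spikes in each of the four
#' memory conditions (successful/unsuccessful x encoding/retrieval) and, per
#' condition, no more than 80% of that condition's segments are empty of
#' spikes.
#'
#' @param spike_table Labelled spike table (see [annotate_session()]) with
#'   `unit_id`, `segment_type`, `segment_id`, `success`.
#' @param segments Labelled segment tibble (with `success`).
#' @param min_spikes Per-condition spike floor (default 25).
#' @param max_empty_frac Maximum fraction of empty segments (default 0.8).
#' @return A tibble: `unit_id`, per-condition counts, `included`, `reason`.
#' @export
apply_inclusion <- function(spike_table, segments, min_spikes = 25,
                            max_empty_frac = 0.8) {
  seg <- dplyr::filter(segments,
                       .data$type %in% c("encoding", "recall_object",
                                         "recall_location"))
  seg$condition <- paste0(ifelse(seg$type == "encoding", "enc_", "ret_"),
                          ifelse(seg$success, "succ", "unsucc"))
  conds <- c("enc_succ", "enc_unsucc", "ret_succ", "ret_unsucc")
  purrr::map_dfr(split(spike_table, spike_table$unit_id), function(st) {
    counts <- integer(4); names(counts) <- conds
    empty_ok <- logical(4); names(empty_ok) <- conds
    for (cd in conds) {
      segs_cd <- seg[seg$condition == cd, ]
      if (nrow(segs_cd) == 0) {
        counts[cd] <- 0L; empty_ok[cd] <- FALSE; next
      }
      n_in_seg <- vapply(segs_cd$segment_id, function(sid) {
        sum(st$segment_id == sid, na.rm = TRUE)
      }, integer(1))
      counts[cd] <- sum(n_in_seg)
      empty_ok[cd] <- mean(n_in_seg == 0) <= max_empty_frac
    }
    included <- all(counts >= min_spikes) && all(empty_ok)
    reason <- if (included) {
      NA_character_
    } else if (any(counts < min_spikes)) {
      paste0("fewer than ", min_spikes, " spikes in ",
             paste(conds[counts < min_spikes], collapse = ","))
    } else {
      paste0("too many empty segments in ",
             paste(conds[!empty_ok], collapse = ","))
    }
    tibble::tibble(unit_id = st$unit_id[1],
                   n_enc_succ = counts[1], n_enc_unsucc = counts[2],
                   n_ret_succ = counts[3], n_ret_unsucc = counts[4],
                   included = included, reason = reason)
  })
}

#' Object-responsiveness test
#'
#' Compares firing rates between each encoding segment and its baseline (the
#' 1.5 s preceding the encoding period, truncated to at least 0.5 s if it
#' overlaps a prior segment) with a paired t-test, ranked within surrogates
#' that randomly swap or keep the encoding/baseline labels of each pair.
#'
#' @param spike_times Spike times, seconds.
#' @param segments Segment tibble (encoding rows used).
#' @param n_surr Surrogates (default 10001).
#' @param alpha Significance level.
#' @param seed Optional integer seed.
#' @return A `contrast_result` row with `significant` (responsive) flag.
#' @export
object_responsive_test <- function(spike_times, segments, n_surr = 10001,
                                   alpha = 0.05, seed = NULL) {
  enc <- dplyr::filter(segments, .data$type == "encoding")
  if (nrow(enc) < 5) stop("need >= 5 encoding segments", call. = FALSE)
  if (!is.null(seed)) {
    old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  prior_ends <- vapply(seq_len(nrow(enc)), function(i) {
    prev <- segments$end_s[segments$end_s <= enc$start_s[i]]
    if (length(prev)) max(prev) else 0
  }, numeric(1))
  base_start <- pmax(enc$start_s - 1.5, prior_ends)
  base_len <- enc$start_s - base_start
  keep <- base_len >= 0.5
  enc <- enc[keep, ]; base_start <- base_start[keep]; base_len <- base_len[keep]
  rate_in <- function(a, b) sum(spike_times >= a & spike_times < b) / (b - a)
  r_enc <- mapply(rate_in, enc$start_s, enc$end_s)
  r_base <- mapply(rate_in, base_start, enc$start_s)
  d <- r_enc - r_base
  m <- length(d)
  tstat <- function(x) mean(x) / (stats::sd(x) / sqrt(length(x)))
  emp <- tstat(d)
  signs <- matrix(sample(c(-1, 1), m * n_surr, replace = TRUE), nrow = n_surr)
  mu_s <- as.vector(signs %*% d) / m
  sd_s <- sqrt((as.vector(signs^2 %*% d^2) - m * mu_s^2) / (m - 1))
  surr <- mu_s / (sd_s / sqrt(m))
  out <- contrast_row("t", emp, surr, "one")
  out$significant <- emp > stats::quantile(surr, 1 - alpha, names = FALSE)
  out
}

#' Group-level firing-rate contrast with condition-swap surrogates
#'
#' Paired t-test on per-unit firing rates between two conditions (e.g. steep
#' versus flat aperiodic slope, or theta oscillation present versus absent),
#' ranked two-sided within surrogates that swap each unit's condition pair
#' with probability 1/2.
#'
#' @param rates_a,rates_b Per-unit rates (Hz) under the two conditions.
#' @param time_a,time_b Total condition durations (s); both must exceed
#'   `min_time_s` for the rates to be considered stable.
#' @param n_surr Surrogates (default 10001).
#' @param sided "two" (default) or "one".
#' @param min_time_s Minimum per-condition occupancy (default 60).
#' @param seed Optional integer seed.
#' @return A `contrast_result` row.
#' @export
firing_rate_contrast <- function(rates_a, rates_b, time_a = Inf, time_b = Inf,
                                 n_surr = 10001, sided = "two",
                                 min_time_s = 60, seed = NULL) {
  if (any(c(time_a, time_b) <= 0)) stop("zero-duration condition", call. = FALSE)
  if (min(time_a) < min_time_s || min(time_b) < min_time_s) {
    stop("each condition must span more than ", min_time_s, " s", call. = FALSE)
  }
  ppc_condition_swap_test(rates_a, rates_b, n_surr = n_surr, sided = sided,
                          seed = seed)
}

# ---- session annotation -----------------------------------------------------

#' Run the preprocessing and annotation stages on a synthetic session
#'
#' Chains preprocessing (waveform subtraction, line-noise removal, demean,
#' artifact masking), generalized-phase estimation, cycle/bout detection and
#' time-resolved aperiodic fitting per wire, then builds one labelled spike
#' table across units: phase, power, segment type and id, success flag,
#' oscillation flag and aperiodic slope per spike.
#'
#' @param session A [gen_session()] result.
#' @param fit_slopes Run the spectral parameterization stage (default TRUE).
#' @param n_potential Monte Carlo size for drop-error normalisation.
#' @return A list: `spikes` (labelled tibble), `segments` (with success),
#'   `behavior`, `phase` (per wire), `cycles`, `bouts`, `frames`, `mask`.
#' @export
annotate_session <- function(session, fit_slopes = TRUE, n_potential = 1e4) {
  stopifnot(inherits(session, "synth_session"))
  behavior <- classify_recall_success(session$behavior,
                                      arena = session$config$arena,
                                      n_potential = n_potential,
                                      seed = session$config$seed)
  segments <- label_segments(session$segments, behavior)
  wires <- names(session$lfp)
  per_wire <- list()
  for (w in wires) {
    units_w <- session$units[session$units$wire_id == session$lfp[[w]]$wire_id, ]
    prep <- preprocess_lfp(session$lfp[[w]],
                           spike_times = units_w$spikes,
                           mean_waveforms = units_w$waveform)
    filt <- bandpass_theta(prep$lfp)
    ps <- generalized_phase(filt)
    ex <- find_extrema_from_phase(ps, filt$samples)
    cb <- score_cycles(filt$samples, ex, filt$fs)
    frames <- NULL
    if (fit_slopes) {
      frames <- fit_frames(timefreq_spectra(prep$lfp, prep$mask))
    }
    per_wire[[w]] <- list(phase = ps, mask = prep$mask, cycles = cb$cycles,
                          bouts = cb$bouts, frames = frames, filt = filt)
  }
  spike_tabs <- purrr::map_dfr(seq_len(nrow(session$units)), function(i) {
    u <- session$units[i, ]
    w <- sub("w", "", u$wire_id)
    pw <- per_wire[[w]]
    st <- assign_spikes(u$spikes[[1]], pw$phase, pw$mask, unit_id = u$unit_id)
    st <- flag_spikes_in_oscillation(st, pw$bouts)
    if (!is.null(pw$frames)) st <- assign_spike_slopes(st, pw$frames)
    st$wire_id <- u$wire_id
    st
  })
  spike_tabs <- label_spike_segments(spike_tabs, segments)
  list(spikes = spike_tabs, segments = segments, behavior = behavior,
       wires = per_wire)
}

label_spike_segments <- function(spike_table, segments) {
  st <- spike_table
  st$segment_id <- NA_integer_
  st$segment_type <- "baseline"
  st$success <- NA
  for (i in seq_len(nrow(segments))) {
    sel <- st$time >= segments$start_s[i] & st$time < segments$end_s[i]
    st$segment_id[sel] <- segments$segment_id[i]
    st$segment_type[sel] <- switch(segments$type[i],
                                   encoding = "encoding",
                                   recall_object = "retrieval",
                                   recall_location = "retrieval",
                                   segments$type[i])
    if ("success" %in% names(segments)) st$success[sel] <- segments$success[i]
  }
  st
}

# ---- locking orchestration --------------------------------------------------

#' Run the locking and conditioning analyses over a cohort
#'
#' For every unit: the circular-shift locking test on all spikes and within
#' each scope (baseline / encoding / retrieval); per-unit PPC pairs for the
#' power, aperiodic-slope and oscillation median splits with group-level
#' condition-swap tests; and the successful-versus-unsuccessful memory
#' contrast. Percentages are reported with their counts and a binomial test
#' against the 5% chance rate.
#'
#' @param annotated An [annotate_session()] result.
#' @param n_surr_locking Circular-shift surrogates per unit (default 1001).
#' @param n_surr_contrast Label-swap surrogates for group tests (default
#'   10001).
#' @param alpha Significance level.
#' @param seed Integer seed.
#' @return A `thetalock_report` list of tidy tibbles: `locking`, `splits`,
#'   `split_tests`, `memory`, `counts`.
#' @export
run_locking_analyses <- function(annotated, n_surr_locking = 1001,
                                 n_surr_contrast = 10001, alpha = 0.05,
                                 seed = 1) {
  st <- annotated$spikes
  units <- unique(st$unit_id)
  scopes <- list(all = rep(TRUE, nrow(st)),
                 baseline = st$segment_type == "baseline",
                 encoding = st$segment_type == "encoding",
                 retrieval = st$segment_type == "retrieval")
  locking <- purrr::map_dfr(units, function(u) {
    purrr::map_dfr(names(scopes), function(sc) {
      sel <- st$unit_id == u & scopes[[sc]]
      if (sum(sel) < 25) {
        return(tibble::tibble(unit_id = u, scope = sc, n = sum(sel),
                              ppc = NA_real_, r = NA_real_, mu = NA_real_,
                              p = NA_real_, significant = NA,
                              n_surrogates = 0L, skipped = "too_few_spikes"))
      }
      wire <- st$wire_id[sel][1]
      ph <- annotated$wires[[sub("w", "", wire)]]$phase$phase
      res <- circshift_locking_test(st$sample[sel], ph,
                                    n_surr = n_surr_locking, alpha = alpha,
                                    seed = seed + match(u, units))
      dplyr::bind_cols(tibble::tibble(unit_id = u, scope = sc), res,
                       tibble::tibble(skipped = NA_character_))
    })
  })

  split_defs <- list(
    power = function(d) median_split(d$log_power),
    slope = function(d) {
      if (!"slope_exponent" %in% names(d)) return(rep(NA_character_, nrow(d)))
      ok <- is.finite(d$slope_exponent)
      out <- rep(NA_character_, nrow(d))
      if (sum(ok) >= 2 && diff(range(d$slope_exponent[ok])) > 0) {
        out[ok] <- median_split(d$slope_exponent[ok])
      }
      out
    },
    oscillation = function(d) ifelse(d$in_oscillation, "high", "low")
  )
  splits <- purrr::map_dfr(names(split_defs), function(sv) {
    purrr::map_dfr(units, function(u) {
      d <- st[st$unit_id == u, ]
      lab <- tryCatch(split_defs[[sv]](d), error = function(e) NULL)
      if (is.null(lab)) lab <- rep(NA_character_, nrow(d))
      hi <- d$phase[!is.na(lab) & lab == "high"]
      lo <- d$phase[!is.na(lab) & lab == "low"]
      tibble::tibble(
        unit_id = u, split = sv,
        n_high = length(hi), n_low = length(lo),
        ppc_high = if (length(hi) >= 2) ppc(hi) else NA_real_,
        ppc_low = if (length(lo) >= 2) ppc(lo) else NA_real_
      )
    })
  })
  split_tests <- purrr::map_dfr(names(split_defs), function(sv) {
    sp <- splits[splits$split == sv, ]
    res <- tryCatch(
      ppc_condition_swap_test(sp$ppc_high, sp$ppc_low,
                              n_surr = n_surr_contrast, sided = "one",
                              seed = seed + 100 + match(sv, names(split_defs))),
      error = function(e) NULL)
    if (is.null(res)) return(tibble::tibble())
    dplyr::bind_cols(tibble::tibble(split = sv), res)
  })

  # successful vs unsuccessful memory contrast (encoding and retrieval)
  memory <- purrr::map_dfr(c("encoding", "retrieval"), function(sc) {
    sp <- purrr::map_dfr(units, function(u) {
      d <- st[st$unit_id == u & st$segment_type == sc & !is.na(st$success), ]
      s1 <- d$phase[d$success]; s0 <- d$phase[!d$success]
      tibble::tibble(unit_id = u,
                     ppc_succ = if (length(s1) >= 2) ppc(s1) else NA_real_,
                     ppc_unsucc = if (length(s0) >= 2) ppc(s0) else NA_real_)
    })
    res <- tryCatch(
      ppc_condition_swap_test(sp$ppc_succ, sp$ppc_unsucc,
                              n_surr = n_surr_contrast, sided = "one",
                              seed = seed + 200 + nchar(sc)),
      error = function(e) NULL)
    if (is.null(res)) return(tibble::tibble())
    dplyr::bind_cols(tibble::tibble(scope = sc), res)
  })

  counts <- dplyr::summarise(
    dplyr::group_by(locking[is.na(locking$skipped), ], .data$scope),
    n_units = dplyr::n(), n_significant = sum(.data$significant),
    pct = 100 * .data$n_significant / .data$n_units,
    binomial_p = binomial_exceedance(.data$n_significant[1], .data$n_units[1]),
    .groups = "drop")

  structure(list(locking = locking, splits = splits,
                 split_tests = split_tests, memory = memory, counts = counts,
                 alpha = alpha, seed = seed),
            class = "thetalock_report")
}

#' @export
print.thetalock_report <- function(x, ...) {
  cat("<thetalock_report>\n")
  cat("Locking (circular-shift surrogate test):\n")
  print(x$counts)
  if (nrow(x$split_tests)) {
    cat("Median-split condition-swap tests:\n")
    print(x$split_tests[, c("split", "empirical", "p")])
  }
  invisible(x)
}

#' Format a significant-unit percentage from its counts
#'
#' Percentages in reports are always recomputed from the underlying counts
#' (rounded only for display), e.g. 571 of 666 prints as "86%".
#'
#' @param k Significant count.
#' @param n Total count.
#' @param digits Display digits (default 0).
#' @return A string like "571 of 666 (86%)".
#' @export
format_count_pct <- function(k, n, digits = 0) {
  sprintf("%d of %d (%s%%)", k, n, formatC(round(100 * k / n, digits),
                                           format = "fg"))
}

# ---- phase-shift analyses ---------------------------------------------------

#' Encoding-versus-retrieval phase-shift test per unit
#'
#' For each unit with at least `min_spikes` spikes in both conditions:
#' compares the phase distribution of all its encoding spikes with that of
#' its retrieval spikes via Watson-Williams, with significance from
#' segment-label-shuffle surrogates (spikes of one segment always move
#' together). The reported angular difference is the circular difference
#' mu_retrieval - mu_encoding, positive meaning a shift toward a later
#' phase at retrieval.
#'
#' @param spike_table Labelled spike table with `unit_id`, `phase`,
#'   `segment_type` ("encoding"/"retrieval"), `segment_id`.
#' @param n_surr Inner surrogates (default 10001).
#' @param min_spikes Per-condition spike floor (default 25).
#' @param alpha Significance level.
#' @param seed Integer seed.
#' @return A `phase_shift_result` tibble: per unit F, p, `significant`,
#'   `mu_encoding`, `mu_retrieval`, `delta_mu`; attributes `n_shifting`,
#'   `binomial_p`.
#' @export
phase_shift_analysis <- function(spike_table, n_surr = 10001, min_spikes = 25,
                                 alpha = 0.05, seed = 1) {
  st <- dplyr::filter(spike_table,
                      .data$segment_type %in% c("encoding", "retrieval"))
  units <- unique(st$unit_id)
  out <- purrr::map_dfr(seq_along(units), function(i) {
    d <- st[st$unit_id == units[i], ]
    enc <- d$segment_type == "encoding"
    if (sum(enc) < min_spikes || sum(!enc) < min_spikes) {
      return(tibble::tibble(unit_id = units[i], n_encoding = sum(enc),
                            n_retrieval = sum(!enc), F = NA_real_,
                            p = NA_real_, significant = NA,
                            mu_encoding = NA_real_, mu_retrieval = NA_real_,
                            delta_mu = NA_real_))
    }
    res <- ww_surrogate_test(d$phase, ifelse(enc, "encoding", "retrieval"),
                             mode = "segment-shuffle", n_surr = n_surr,
                             segment_id = d$segment_id, alpha = alpha,
                             seed = seed + i)
    mu_e <- circ_mean_r(d$phase[enc])$mu
    mu_r <- circ_mean_r(d$phase[!enc])$mu
    tibble::tibble(unit_id = units[i], n_encoding = sum(enc),
                   n_retrieval = sum(!enc), F = res$empirical, p = res$p,
                   significant = res$significant,
                   mu_encoding = mu_e, mu_retrieval = mu_r,
                   delta_mu = wrap_pi(mu_r - mu_e))
  })
  tested <- !is.na(out$significant)
  attr(out, "n_shifting") <- sum(out$significant[tested])
  attr(out, "n_tested") <- sum(tested)
  attr(out, "binomial_p") <- if (any(tested)) {
    binomial_exceedance(sum(out$significant[tested]), sum(tested), alpha)
  } else NA_real_
  class(out) <- c("phase_shift_result", class(out))
  out
}

# Fast per-unit phase-shift test from precomputed per-segment circular sums.
# cs: matrix [n_seg x 3] of (sum cos, sum sin, n); lab_a: logical per segment.
ww_shift_test_fast <- function(phases, seg_of_spike, enc_segment, n_surr,
                               alpha) {
  segs <- sort(unique(seg_of_spike))
  idx <- match(seg_of_spike, segs)
  cs <- cbind(
    rowsum(cos(phases), idx), rowsum(sin(phases), idx),
    tabulate(idx, length(segs))
  )
  is_a <- unname(enc_segment[as.character(segs)])
  ntot <- length(phases)
  ctot <- sum(cs[, 1]); stot <- sum(cs[, 2])
  na_e <- sum(cs[is_a, 3])
  if (na_e < 2 || ntot - na_e < 2) return(NA)
  emp <- ww_f_from_sums(sum(cs[is_a, 1]), sum(cs[is_a, 2]), na_e,
                        ctot, stot, ntot)
  n_seg <- length(segs); n_a <- sum(is_a)
  # selection matrix for the segment-label shuffles
  M <- matrix(0, n_surr, n_seg)
  for (s in seq_len(n_surr)) M[s, sample.int(n_seg, n_a)] <- 1
  sums <- M %*% cs
  ok <- sums[, 3] >= 2 & (ntot - sums[, 3]) >= 2
  while (any(!ok)) { # redraw degenerate surrogates
    for (s in which(!ok)) {
      M[s, ] <- 0; M[s, sample.int(n_seg, n_a)] <- 1
    }
    sums <- M %*% cs
    ok <- sums[, 3] >= 2 & (ntot - sums[, 3]) >= 2
  }
  surr <- ww_f_from_sums(sums[, 1], sums[, 2], sums[, 3], ctot, stot, ntot)
  emp > stats::quantile(surr, 1 - alpha, names = FALSE)
}

#' Empirical chance level of the phase-shift analysis
#'
#' Builds surrogate datasets in which each unit's spike phases are
#' concatenated in order of occurrence, circularly shifted by a random lag,
#' and reassigned to the same encoding and retrieval segments; the full
#' per-unit Watson-Williams shift test (with inner segment-label shuffles)
#' is then run on every surrogate dataset and the percentage of flagged
#' units recorded. On data with no true encoding-retrieval shift the mean
#' of this distribution should match the nominal alpha level.
#'
#' @param spike_table Labelled spike table (see [phase_shift_analysis()]).
#' @param n_datasets Number of surrogate datasets (default 1001).
#' @param n_surr_inner Inner shuffles per unit test (default 10001).
#' @param min_spikes Per-condition spike floor (default 25).
#' @param alpha Significance level (default 0.05).
#' @param seed Integer seed.
#' @return A list: `pct_flagged` (per dataset), `mean_pct`, `n_units`.
#' @export
phase_shift_chance_control <- function(spike_table, n_datasets = 1001,
                                       n_surr_inner = 10001, min_spikes = 25,
                                       alpha = 0.05, seed = 1) {
  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  st <- dplyr::filter(spike_table,
                      .data$segment_type %in% c("encoding", "retrieval"))
  st <- dplyr::arrange(st, .data$unit_id, .data$time)
  units <- split(st, st$unit_id)
  # precompute per-unit structures; drop units failing the spike floor
  prep <- purrr::compact(purrr::map(units, function(d) {
    enc <- d$segment_type == "encoding"
    if (sum(enc) < min_spikes || sum(!enc) < min_spikes) return(NULL)
    seg_ids <- sort(unique(d$segment_id))
    list(phases = d$phase,
         seg_of_spike = d$segment_id,
         enc_segment = stats::setNames(
           vapply(seg_ids, function(s) d$segment_type[d$segment_id == s][1],
                  character(1)) == "encoding",
           seg_ids))
  }))
  n_units <- length(prep)
  if (n_units == 0) stop("no unit passes the spike floor", call. = FALSE)
  pct <- vapply(seq_len(n_datasets), function(ds) {
    flags <- vapply(prep, function(u) {
      n <- length(u$phases)
      lag <- sample.int(n - 1L, 1)
      shifted <- u$phases[((seq_len(n) - 1L + lag) %% n) + 1L]
      res <- ww_shift_test_fast(shifted, u$seg_of_spike,
                                u$enc_segment, n_surr_inner, alpha)
      isTRUE(res)
    }, logical(1))
    100 * mean(flags)
  }, numeric(1))
  list(pct_flagged = pct, mean_pct = mean(pct), n_units = n_units)
}
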