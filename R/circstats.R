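#' Circular mean and resultant vector length
#'
#' Summarises a set of phase angles by the direction and modulus of their
#' mean unit vector. `r` (the mean resultant vector length, MRVL) is 1 when
#' all phases coincide and 0 for perfectly dispersed phases.
#'
#' @param phases Numeric vector of angles in radians.
#' @return A list with `mu` (circular mean in (-pi, pi]) and `r` (in [0, 1]).
#' @examples
#' circ_mean_r(c(0, pi / 2))
#' @export
circ_mean_r <- function(phases) {
  if (length(phases) < 1L || !is.numeric(phases)) {
    stop("`phases` must be a non-empty numeric vector", call. = FALSE)
  }
  s <- sum(sin(phases))
  c_ <- sum(cos(phases))
  list(mu = atan2(s, c_), r = sqrt(s^2 + c_^2) / length(phases))
}

#' Pairwise phase consistency
#'
#' The mean cosine of all pairwise phase differences among spike phases,
#' computed through the closed form \eqn{(R^2 - n) / (n (n - 1))} where
#' \eqn{R} is the modulus of the summed unit vectors. Unlike the Rayleigh
#' statistic, PPC is unbiased by spike count; it ranges over [-1, 1].
#'
#' @param phases Numeric vector of angles in radians, length >= 2.
#' @return A single PPC value.
#' @export
ppc <- function(phases) {
  n <- length(phases)
  if (n < 2L) stop("PPC requires at least 2 phases", call. = FALSE)
  R2 <- sum(cos(phases))^2 + sum(sin(phases))^2
  (R2 - n) / (n * (n - 1))
}

#' Rayleigh test for circular non-uniformity
#'
#' The Rayleigh statistic z = n * r^2, with a p-value from the standard
#' large-sample approximation including the finite-n correction. Note z is
#' strongly biased by spike count (it grows linearly in n at fixed r), which
#' is why locking strength comparisons in this package default to PPC.
#'
#' @param phases Numeric vector of angles in radians.
#' @return A list with `z`, `p`, `n` and `r`.
#' @export
rayleigh <- function(phases) {
  n <- length(phases)
  if (n < 1L) stop("`phases` must be non-empty", call. = FALSE)
  r <- circ_mean_r(phases)$r
  z <- n * r^2
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - (n * r)^2)) - (1 + 2 * n))
  list(z = z, p = min(1, p), n = n, r = r)
}

# rank-based p: guarantees p > 0 and agrees with the "exceeds the 95th
# percentile" significance rule for one-sided tests
rank_p <- function(empirical, surrogates, sided = c("one", "two")) {
  sided <- match.arg(sided)
  if (sided == "one") {
    (1 + sum(surrogates >= empirical)) / (length(surrogates) + 1)
  } else {
    (1 + sum(abs(surrogates) >= abs(empirical))) / (length(surrogates) + 1)
  }
}

#' Circular-shift surrogate test of theta-phase locking
#'
#' Ranks the empirical PPC of the spike phases within surrogate PPC values
#' obtained by circularly rotating the full phase array relative to the spike
#' sample indices. The rotation preserves the autocorrelation of the phase
#' series and the spike train's temporal structure, destroying only their
#' alignment; rotation by lag 0 is excluded so the empirical value is never
#' compared against itself.
#'
#' @param spike_samples Integer sample indices of spikes (1-based).
#' @param phase Numeric phase array (radians), one value per LFP sample.
#' @param n_surr Number of surrogate rotations (default 1001).
#' @param alpha Significance level (default 0.05).
#' @param seed Optional integer seed for the rotation lags.
#' @return A `locking_result` tibble row: `n`, `ppc`, `r`, `mu`, `p`,
#'   `significant`, `n_surrogates`.
#' @export
circshift_locking_test <- function(spike_samples, phase, n_surr = 1001,
                                   alpha = 0.05, seed = NULL) {
  n <- length(spike_samples)
  if (n < 2L) stop("need at least 2 spikes", call. = FALSE)
  N <- length(phase)
  if (diff(range(phase)) < .Machine$double.eps) {
    stop("phase array is constant; surrogate null is degenerate", call. = FALSE)
  }
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  emp_phases <- phase[spike_samples]
  emp <- ppc(emp_phases)
  mr <- circ_mean_r(emp_phases)
  lags <- sample.int(N - 1L, n_surr, replace = TRUE) # lag in [1, N-1]
  surr <- vapply(lags, function(lag) {
    idx <- ((spike_samples - 1L + lag) %% N) + 1L
    ppc(phase[idx])
  }, numeric(1))
  p <- rank_p(emp, surr, "one")
  tibble::tibble(
    n = n, ppc = emp, r = mr$r, mu = mr$mu, p = p,
    significant = emp > stats::quantile(surr, 1 - alpha, names = FALSE),
    n_surrogates = n_surr
  )
}

#' Rayleigh z-difference shuffle test
#'
#' Compares locking strength between two spike-phase groups through the
#' difference of Rayleigh z-values, ranked within surrogates that permute the
#' pooled phases into groups of the original sizes (spike counts are
#' preserved in every surrogate round).
#'
#' @param phases_a,phases_b Phase vectors (radians) of the two conditions.
#' @param n_surr Number of label shuffles (default 10001).
#' @param sided "one" (default; tests z_A > z_B) or "two".
#' @param seed Optional integer seed.
#' @return A `contrast_result` tibble row with the empirical delta-z, the
#'   rank p-value and surrogate summary.
#' @export
rayleigh_diff_shuffle_test <- function(phases_a, phases_b, n_surr = 10001,
                                       sided = "one", seed = NULL) {
  na <- length(phases_a); nb <- length(phases_b)
  if (na < 1L || nb < 1L) stop("both groups must be non-empty", call. = FALSE)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  zdiff <- function(a, b) rayleigh(a)$z - rayleigh(b)$z
  emp <- zdiff(phases_a, phases_b)
  pooled <- c(phases_a, phases_b)
  n <- na + nb
  surr <- vapply(seq_len(n_surr), function(i) {
    idx <- sample.int(n, na)
    zdiff(pooled[idx], pooled[-idx])
  }, numeric(1))
  contrast_row("delta_z", emp, surr, sided)
}

contrast_row <- function(statistic, empirical, surrogates, sided) {
  tibble::tibble(
    statistic = statistic,
    empirical = empirical,
    n_surrogates = length(surrogates),
    exceedance_rank = sum(surrogates >= empirical),
    p = rank_p(empirical, surrogates, sided),
    sided = sided
  )
}

#' Paired-t condition-swap test on per-unit PPC pairs
#'
#' A paired t-test on per-unit PPC differences between two conditions, with
#' significance from surrogates that independently swap each unit's condition
#' pair with probability 1/2 (sign-flip null).
#'
#' @param ppc1,ppc2 Per-unit PPC values under conditions 1 and 2 (same order).
#' @param n_surr Number of label swaps (default 10001).
#' @param sided "one" (default; tests condition 1 > condition 2) or "two".
#' @param seed Optional integer seed.
#' @return A `contrast_result` tibble row (statistic "t"); `n_units` records
#'   how many complete pairs entered the test.
#' @export
ppc_condition_swap_test <- function(ppc1, ppc2, n_surr = 10001,
                                    sided = "one", seed = NULL) {
  ok <- is.finite(ppc1) & is.finite(ppc2)
  if (sum(!ok) > 0) {
    message(sum(!ok), " unit(s) dropped: PPC undefined in one condition")
  }
  d <- ppc1[ok] - ppc2[ok]
  m <- length(d)
  if (m < 2L) stop("need >= 2 units with both conditions defined", call. = FALSE)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  tstat <- function(x) mean(x) / (stats::sd(x) / sqrt(length(x)))
  emp <- tstat(d)
  signs <- matrix(sample(c(-1, 1), m * n_surr, replace = TRUE), nrow = n_surr)
  surr_mean <- signs %*% d / m
  surr_sd <- sqrt((as.vector(signs^2 %*% d^2) - m * surr_mean^2) / (m - 1))
  surr <- as.vector(surr_mean) / (surr_sd / sqrt(m))
  out <- contrast_row("t", emp, surr, sided)
  out$n_units <- m
  out
}

# maximum-likelihood-style estimate of the von Mises concentration from r
est_kappa <- function(r) {
  if (r < 0.53) {
    2 * r + r^3 + 5 * r^5 / 6
  } else if (r < 0.85) {
    -0.4 + 1.39 * r + 0.43 / (1 - r)
  } else {
    1 / (r^3 - 4 * r^2 + 3 * r)
  }
}

#' Watson-Williams test for equality of mean directions
#'
#' The circular analogue of a two-sample test of means, with the usual
#' concentration correction factor 1 + 3/(8 kappa). No assumption gating is
#' applied here: inference in this package comes from ranking the F statistic
#' in surrogate distributions (see [ww_surrogate_test()]), which supplies
#' validity without the parametric assumptions.
#'
#' @param phases_a,phases_b Phase vectors (radians), each of length >= 2.
#' @return The Watson-Williams F statistic.
#' @export
watson_williams <- function(phases_a, phases_b) {
  na <- length(phases_a); nb <- length(phases_b)
  if (na < 2L || nb < 2L) stop("both groups need n >= 2", call. = FALSE)
  n <- na + nb
  Ra <- na * circ_mean_r(phases_a)$r
  Rb <- nb * circ_mean_r(phases_b)$r
  R <- n * circ_mean_r(c(phases_a, phases_b))$r
  rw <- (Ra + Rb) / n
  if (rw < 1e-12) stop("pooled resultant ~ 0; correction factor undefined", call. = FALSE)
  kk <- est_kappa(rw)
  K <- 1 + 3 / (8 * kk)
  K * ((n - 2) * (Ra + Rb - R)) / (n - (Ra + Rb))
}

# Vectorised Watson-Williams F from group-A circular sums. ca/sa are vectors
# of sum(cos)/sum(sin) over group A for each surrogate; na may be scalar.
ww_f_from_sums <- function(ca, sa, na, ctot, stot, ntot) {
  cb <- ctot - ca; sb <- stot - sa
  nb <- ntot - na
  Ra <- sqrt(ca^2 + sa^2)
  Rb <- sqrt(cb^2 + sb^2)
  R <- sqrt(ctot^2 + stot^2)
  rw <- (Ra + Rb) / ntot
  kk <- vapply(rw, est_kappa, numeric(1))
  K <- 1 + 3 / (8 * kk)
  K * ((ntot - 2) * (Ra + Rb - R)) / (ntot - (Ra + Rb))
}

#' Surrogate-rank Watson-Williams test
#'
#' Ranks the empirical Watson-Williams F within a surrogate distribution
#' built under one of two exchangeability schemes:
#' \describe{
#'   \item{"segment-shuffle"}{condition labels are permuted across
#'     *segments*, so all spikes of one segment always move together. This
#'     preserves within-segment phase dependence and is the null for
#'     encoding-versus-retrieval phase-shift testing. Requires `segment_id`.}
#'   \item{"spike-reassign"}{each spike is independently reassigned to a
#'     condition while maintaining the original group spike counts; the null
#'     for successful-versus-unsuccessful preferred-phase comparisons.}
#' }
#' Surrogates that produce an empty or singleton group are redrawn (and
#' counted) so the surrogate count stays exact.
#'
#' @param phases Phase vector (radians) for all spikes.
#' @param labels Two-level factor/character/logical condition label per spike.
#' @param mode "segment-shuffle" or "spike-reassign".
#' @param n_surr Number of surrogates (default 10001).
#' @param segment_id Segment identifier per spike (segment-shuffle mode).
#' @param alpha Significance level for the 95th-percentile rule.
#' @param seed Optional integer seed.
#' @return A `contrast_result` tibble row (statistic "F") with an added
#'   `significant` flag (empirical F above the (1-alpha) surrogate quantile).
#' @export
ww_surrogate_test <- function(phases, labels, mode = c("segment-shuffle", "spike-reassign"),
                              n_surr = 10001, segment_id = NULL, alpha = 0.05,
                              seed = NULL) {
  mode <- match.arg(mode)
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (length(lev) != 2L) stop("`labels` must have exactly 2 levels", call. = FALSE)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  is_a <- labels == lev[1]
  emp <- watson_williams(phases[is_a], phases[!is_a])
  ctot <- sum(cos(phases)); stot <- sum(sin(phases)); ntot <- length(phases)

  if (mode == "spike-reassign") {
    na <- sum(is_a)
    surr <- vapply(seq_len(n_surr), function(i) {
      idx <- sample.int(ntot, na)
      ca <- sum(cos(phases[idx])); sa <- sum(sin(phases[idx]))
      ww_f_from_sums(ca, sa, na, ctot, stot, ntot)
    }, numeric(1))
  } else {
    if (is.null(segment_id)) stop("segment-shuffle mode requires `segment_id`", call. = FALSE)
    seg <- split(seq_along(phases), segment_id)
    seg_c <- vapply(seg, function(i) sum(cos(phases[i])), numeric(1))
    seg_s <- vapply(seg, function(i) sum(sin(phases[i])), numeric(1))
    seg_n <- lengths(seg)
    # a segment's label is the label of its spikes (labels constant per segment)
    seg_lab <- vapply(seg, function(i) labels[i[1]], character(1))
    n_seg <- length(seg)
    n_seg_a <- sum(seg_lab == lev[1])
    surr <- numeric(n_surr)
    i <- 1L
    while (i <= n_surr) {
      idx <- sample.int(n_seg, n_seg_a)
      na <- sum(seg_n[idx])
      if (na < 2L || ntot - na < 2L) next # redraw empty/singleton group
      surr[i] <- ww_f_from_sums(sum(seg_c[idx]), sum(seg_s[idx]), na,
                                ctot, stot, ntot)
      i <- i + 1L
    }
  }
  out <- contrast_row("F", emp, surr, "one")
  out$significant <- emp > stats::quantile(surr, 1 - alpha, names = FALSE)
  out
}

#' One-sided exact binomial exceedance probability
#'
#' P(X >= k) for X ~ Binomial(n, p0); used to test whether the fraction of
#' significant units in a cohort exceeds the chance rate.
#'
#' @param k Number of successes observed.
#' @param n Number of trials.
#' @param p0 Chance probability (default 0.05).
#' @return The exact upper-tail probability.
#' @export
binomial_exceedance <- function(k, n, p0 = 0.05) {
  stopifnot(k >= 0, k <= n)
  stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
}

#' Median split into high/low groups
#'
#' Values strictly above the median are labelled "high", all others
#' (including exact ties with the median) "low". The tie rule is documented
#' rather than randomised so that splits are reproducible.
#'
#' @param values Numeric vector, length >= 2, not all identical.
#' @return Character vector of "high"/"low" labels.
#' @export
median_split <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values", call. = FALSE)
  if (diff(range(values)) < .Machine$double.eps) {
    stop("all values identical; median split undefined", call. = FALSE)
  }
  ifelse(values > stats::median(values), "high", "low")
}

# Save/restore .Random.seed so seeded helpers do not disturb the caller's RNG
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

# wrap angles into (-pi, pi]
wrap_pi <- function(x) {
  w <- (x + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}
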