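---
title: "Methods: broadband theta-phase locking and its surrogate inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: broadband theta-phase locking and its surrogate inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(thetalock)
```

This vignette documents the models, numerical choices and design decisions
behind `thetalock`, in the spirit of a methods section: what each stage
assumes, which parameters matter, and what the synthetic-data tests do and
do not establish about real recordings.

## The signal model

Human medial-temporal LFP is modelled as the sum of an aperiodic 1/f-like
background (power ∝ f^−χ, with χ typically 0.5–2), transient theta bursts
of drifting frequency within 1–10 Hz, line noise at 50 Hz and harmonics,
and occasional high-amplitude pathological transients. Spiking is modelled
as an inhomogeneous Poisson process whose intensity is modulated by the
theta phase θ(t):

λ(t) = r · 2π · f_vM(θ(t); μ, κ),

where f_vM is the von Mises density with preferred phase μ and
concentration κ. The 2π normalisation keeps the mean rate at r under
uniform phase occupancy, and κ = 0 reduces exactly to a homogeneous
Poisson train. Alternative unit models are an unmodulated Poisson train
and a *theta-resonant* train (spikes at multiples of 1/f with Gaussian
jitter, independent of the LFP) — the latter exists to verify that
intrinsic rhythmicity alone does not register as spike–field locking under
circular-shift inference.

## Preprocessing

1. **Spike-waveform subtraction.** Each unit's mean action-potential
   waveform is subtracted at its spike times, with the first and last 10%
   of the snippet linearly tapered to zero (the taper fraction is a
   package choice; it suppresses step edges and is configurable).
2. **Resampling to 2 kHz** via polyphase Kaiser-windowed sinc filtering.
3. **Line-noise removal**: a zero-phase FIR band-stop at 48–52, 98–102 and
   148–152 Hz. The normative contract is ≥ 30 dB attenuation at the notch
   centres and < 1 dB ripple below 40 Hz; the kernel order (≈ fs) is
   whatever meets that contract. Zero phase is obtained exactly by
   compensating the symmetric kernel's group delay after circular FFT
   convolution; circular edges keep filtering exactly linear in the DC
   component, so filtering and demeaning commute to machine precision.
   The first/last filter-length samples are wrap-contaminated and should
   not be interpreted.
4. **Demeaning.**
5. **Artifact masking.** A sample is flagged when any of three robust
   z-scores (median/MAD) exceeds its threshold: the amplitude envelope
   (z > 6), the signed first difference (|z| > 6), or the log₁₀ 25–80 Hz
   band power in a 100 ms window (z > 5). Log power is used because raw
   band power is strongly right-skewed even on clean traces. Flags are
   padded by ±250 ms and merged; spikes inside masked intervals are
   excluded from all statistics. The thresholds are package defaults
   (exposed as arguments); the three-detector OR rule and the padding are
   fixed.

## Generalized phase

The preprocessed trace is filtered at 1–10 Hz with a zero-phase FIR filter
(order 6000 at 2 kHz, scaled proportionally at other rates) and the
analytic signal is computed by a single full-trace Hilbert transform.
Phase is the analytic angle (0 at peaks, ±π at troughs — all polar
summaries use this convention); instantaneous power is the squared
magnitude.

Because the band is broad, low-amplitude epochs can show phase progression
slower than 1 Hz or outright reversals. Instantaneous frequency is
estimated by centred differences of the unwrapped phase (one-sided at the
edges); samples below 1 Hz (including negative) are marked. A reversal
leaves the unwrapped phase *below* its pre-epoch level, so each marked
epoch is extended until the phase re-attains its onset value; the epoch is
then bridged with a Fritsch–Carlson monotone cubic (shape-preserving
PCHIP) through the neighbouring valid samples and rewrapped. Untouched
samples keep their analytic phase bitwise; `interp_mask` records exactly
what was replaced. Epochs touching the trace boundary are extrapolated
linearly from the nearest valid trend and flagged. These boundary and
estimator choices are package decisions — the procedure is stated in the
literature without them.

Each spike is annotated with the temporally closest sample's phase and
power (ties resolve to the earlier sample).

## Oscillation detection

Cycles run peak-to-peak, with peaks at upward zero-crossings of the
generalized phase and troughs at ±π wraps; repeated same-kind extrema are
resolved by amplitude on the filtered trace so the sequence strictly
alternates. Per cycle: amplitude (mean of decay and rise excursions),
period, amplitude consistency and period consistency (worst min/max ratio
among the flank or period pairs shared with neighbouring cycles, following
the published cycle-by-cycle definitions), and monotonicity (fraction of
same-sign sample differences on the flanks). A cycle is oscillatory iff
amplitude consistency ≥ 0.3, period consistency ≥ 0.5, monotonicity ≥ 0.6
and its amplitude exceeds the session-wide 20th percentile (ties at the
percentile pass, so constant-amplitude signals are not fragmented by
numerical noise). Runs of ≥ 2 oscillatory cycles become bouts with
frequency = n_cycles / duration. The percentile population (all cycles of
the wire over the whole session) is a package decision consistent with the
session-wide framing of the other statistics. Bout intervals are half-open
in samples.

On 1–10 Hz-filtered pink noise alone, roughly a quarter to a third of time
passes these criteria — filtered noise genuinely looks rhythmic at these
thresholds. Interpretation of oscillation-conditioned results should rest
on the in/out *contrast*, not on occupancy in isolation.

## Time-resolved spectral parameterization

Short-time spectra use 1-s Hann windows at 50% overlap with per-window
linear detrending (without it, leakage from sub-window fluctuations
inflates the lowest bins of steep spectra and biases the exponent upward
by up to +0.2 at χ = 2; with it, recovery is within ±0.1). Every 500 ms
the spectra of five consecutive windows are averaged, so each frame spans
3 s. Frames overlapping any artifact interval are invalid (strictest
reading). The aperiodic fit is log₁₀ P = b − χ·log₁₀ f over 1–40 Hz:
ordinary least squares, then a refit on the points in the lower half of
residuals, which suppresses peak contamination. Up to three Gaussian peaks
are extracted from the flattened spectrum, largest first; a peak needs
height > 0.5, SNR > 2 (height over the SD of the flattened residual — the
SNR definition is a package decision), SD within 2–6 Hz, and must not sit
within one SD of a larger peak's centre or of the 1/40 Hz edges. "Steep
slope" throughout means larger exponent χ; median splits are on χ. Each
spike inherits the exponent of the frame whose 500-ms step contains it.

## Locking statistics and surrogate inference

- PPC via the closed form (R² − n)/(n(n − 1)), verified in tests against
  the O(n²) pair enumeration to 1e−12. PPC is unbiased in spike count;
  Rayleigh z = n·r² is retained for the Δz analyses with that bias
  documented.
- **Circular-shift test**: the phase array is rotated by a uniform lag in
  [1, N − 1] (never 0) and PPC recomputed at fixed spike samples, 1001
  surrogates by default; significant iff the empirical PPC exceeds the
  95th surrogate percentile.
- **Contrast tests**: Δz label shuffles preserving group sizes; per-unit
  PPC condition swaps (sign-flip null) for power/slope/oscillation splits
  and memory contrasts; Watson–Williams F (with the 1 + 3/(8κ̂)
  correction, no parametric gating) ranked in segment-shuffle or
  spike-reassignment surrogates. Surrogates producing an empty or
  singleton group are redrawn so the surrogate count stays exact.
- Rank p-values are p = (1 + #{surr ≥ emp}) / (n_surr + 1), which is
  strictly positive and consistent with the percentile rule. Median-split
  ties go to "low" (documented, configurable at the call site).

The **chance-level control** for the phase-shift analysis concatenates
each unit's encoding and retrieval phases in order of occurrence,
circularly shifts the list by a random lag, reassigns the shifted phases
to the original segments, and reruns the full per-unit test; the mean
flagged percentage across surrogate datasets estimates the analysis's
empirical alpha. With 200 inner surrogates per test the percentile
threshold is slightly granular, so values a few tenths of a percentage
point above the nominal 5% are expected.

## Problem sizes and defaults

The synthetic study conditions are: 2 kHz sampling, pink exponent 1,
background SD 30 µV, bursts at 10/min drawn from 3–5 Hz (4–12 cycles,
amplitude twice the background SD, linear drift SD 0.5 Hz, one-cycle Hann
ramps), 50 Hz line noise at 10 µV with harmonics, 20 trials with 2–3
two-second encoding events, a 6.6-s distractor and 5-s recalls
(object/location alternating by trial), and success probability rising
linearly from 0.4 to 0.8. Drop errors mix Rayleigh-distributed accurate
responses with uniform guesses over a 100×100 rectangle arena;
normalisation ranks the observed error within uniformly sampled potential
responses per true location (the sampling scheme is a package decision —
it makes the metric location-dependent, as ranking implies). Test suites
run at reduced but stated scales: 240-s traces for detector calibration,
60-s traces × 20 seeds for exponent recovery, 100-unit cohorts with 200
surrogate datasets × 200 inner shuffles for the chance-level control.
These sizes were chosen so the full suite runs on a single CPU in minutes
while keeping Monte-Carlo error well inside each tolerance.

## What the synthetic tests do not show

The generator makes no claim about the biophysics of human LFP: bursts are
additive Hann-enveloped sinusoids, noise is exactly 1/f with Gaussian
amplitudes, wires are independent, and spike sorting is noiseless.
Passing recovery tests therefore demonstrates the *estimators* are
correct and calibrated under known ground truth — not that real data meet
the generator's assumptions. In particular, real theta bouts need not be
sinusoidal (waveform asymmetry is explicitly out of scope), real IEDs are
more varied than the biphasic template, and the aperiodic exponent of
real recordings varies on time scales the stationary generator does not
emulate (the conditioning tests construct that variation explicitly from
alternating-exponent blocks).

## Known limitations

- The generalized-phase implementation follows the stated procedure only;
  further refinements published for the original method (e.g. additional
  low-pass filtering of the analytic signal) are deliberately omitted.
- No knee-parameter aperiodic model; spectra with a bend within 1–40 Hz
  will bias χ.
- The Watson–Williams correction is undefined when the pooled resultant
  is ~0 with tiny samples; the function errors rather than guessing, and
  surrogate ranking supplies validity everywhere else.
- Fit quality of spectral frames is reported (RMS in log space) but not
  thresholded; downstream filtering is the user's decision.
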