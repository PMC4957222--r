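---
title: "Cardiac phase-locking of sleep slow waves: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cardiac phase-locking of sleep slow waves: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsewave)
```

## The question and the statistic

Frequency-domain NIRS recordings carry a strong cardiac pulsation: with every
heart beat, arterial blood volume rises and light absorption with it, so the
detected light intensity (the AC amplitude columns) dips once per cardiac
cycle. `pulsewave` asks whether the onsets of individual sleep slow waves are
phase-locked to that ongoing pulsation, and provides the machinery to answer
it for a single night of simultaneous EEG + ECG + NIRS:

1. detect slow waves on the negative envelope of six EEG channels;
2. time-lock the raw NIRS (or ECG) signal to a wave landmark and average
   thousands of trials into an evoked response (nERP / eERP);
3. correlate the evoked trace with a sine of the participant's mean N3 heart
   rate, nadir at the event, maximizing Pearson *r* over a bounded lag range;
4. compare the observed *r* with the same statistic recomputed for
   event sets drawn at random latencies (a surrogate-latency permutation
   test).

The two reported measures are the correlation `r` and the phase delay: the
signed lag, in seconds, from the sine's nadir to the event, positive when the
pulsation nadir precedes the wave onset. The p-value is the plain proportion
of surrogate correlations at least as large as the observed one, so it can
be exactly 0; a `(k+1)/(n+1)` variant is available. Because every surrogate
statistic also takes the maximum over lags, the test is conservative by
construction.

## Slow-wave detection

Detection operates on the *canonical wave*: the pointwise minimum (negative
envelope) of the six channels after zero-phase 1–4 Hz Butterworth filtering.
Zero-phase (forward–backward) filtering is used everywhere so that landmark
times are not shifted by the filter's phase response; signals are
odd-reflection padded so there are no edge transients. Candidate waves are
maximal negative excursions of the envelope between a downward and the
subsequent upward zero-crossing (crossing times linearly interpolated
between samples), restricted to N2/N3 epochs outside marked
arousals/artifacts. A candidate becomes a slow wave when

* its negative peak reaches `theta = median(neg) − 5 × scale(neg)` computed
  over the negative-valued masked envelope samples,
* its negative half-wave lasts 250–1250 ms, and
* its steepest rising slope (between negative peak and upward zero-crossing)
  reaches the within-night 90th percentile of candidate slopes,

and at least one individual channel co-expresses it (bounded-lag correlation
with the envelope segment ≥ 0.9 within ±100 ms, channel minimum negative and
≥ 10% of the amplitude threshold). Waves with no supporting channel are
discarded as false positives.

Two points in this recipe are genuinely open and we had to commit:

* **Scale estimator for the amplitude rule.** With `scale = sd` the waves
  themselves inflate the spread of the negative samples: at ~8 waves/min and
  a ~0.45 s negative lobe, deep waves contribute enough variance that
  `5 × SD` grows almost in proportion to the wave amplitude, and the
  threshold chases the very events it is meant to select — detection of a
  homogeneous wave population is then knife-edge at *any* amplitude. We
  therefore default to the Gaussian-consistent MAD, which anchors the
  threshold to the background activity and preserves the rule's intent
  ("five deviations below the median negative activity"). `amp_scale =
  "sd"` switches back to the literal rule, and `amp_stat = "peaks"` computes
  both statistics over candidate peak amplitudes instead of samples.
* **Population for the slope percentile.** Taking the 90th percentile over
  candidates that already passed amplitude + wavelength would by definition
  discard 90% of real waves. We default to the percentile over *all*
  candidate half-waves — in N2/N3 the sub-threshold delta activity supplies
  hundreds of shallow candidates per night, so real waves sit in the upper
  tail and survive. `slope_population = "passing"` gives the other reading.

Detection criteria are all relative (threshold, percentile, correlation), so
detection is invariant to a global amplitude rescaling of the EEG; this is
tested.

## Synchronization, epoching, averaging

The NIRS device runs on its own clock at a nominal 36/42/52 Hz that may
deviate by tens of ppm. The device marks its first and last sample on the
EEG clock through a trigger cable; `build_sync_map()` fits the exact linear
map `t_eeg = intercept + slope × index` through that trigger pair, which
absorbs any constant rate deviation of either device. Events are placed at
the *nearest* NIRS sample — the NIRS trace itself is never resampled,
interpolated or filtered; the only manipulation of NIRS epochs is an
independent least-squares line removal per trial (which strips the slow
instrumental drift and nothing else; the detrend is one fixed linear
projection, so it commutes with averaging — the permutation engine exploits
exactly this, and a test pins the equality against the explicit per-trial
path). The evoked window is 3 s before to 3 s after the event. The noise
estimate used only for display is the mean over time of the per-sample
across-trial SD (`noise_method = "per_trial"` gives the alternative
reading); the correlation statistic is invariant to this normalization, and
statistics always use the raw mean trace.

When channel pools are analyzed (e.g., the eight brain-sensor AC columns),
pooling trials across channels with equal trial counts equals epoching the
mean of the channel signals, again by linearity; both routes are implemented
and their equality is tested.

## The bounded-lag statistic and its null

The template is `s(t) = −cos(2π f t)` on the evoked grid with `f` the mean
N3 heart rate estimated from detected R peaks (energy-based detector,
squared 10–40 Hz band, 250 ms refractory; invariant to gain and polarity).
`bounded_xcorr()` computes the Pearson correlation on the overlapping region
at every integer-sample lag within the bound and returns the maximum, ties
toward the smallest |lag|. The default lag bound is half the template
period: beyond half a cycle, lags alias onto the adjacent cycle, so a wider
bound adds nothing but multiplicity ("half the wavelength" of the reference
oscillation is ambiguous in the tradition this follows; the bound is a
config parameter).

Surrogate event sets are drawn uniformly with replacement from the same
N2/N3, artifact-free, window-interior sample set the real events live in,
with matched trial count. Observed and surrogate statistics run through one
code path (`evoked_stat_engine`), differing only in the event times.

## The synthetic-data generator

The generator exists so that every stage is testable with known ground
truth. Its defaults are the study conditions; they are chosen once, for
realism, and stated here:

* **Cardiac cycle** — i.i.d. Gaussian inter-beat intervals (truncated ±3 SD)
  around 60 bpm with 3 bpm beat-to-beat variability; cardiac phase runs
  0→2π within each beat, phase 0 at the R peak. ECG morphology is a sum of
  Gaussian bumps (P, Q, R, S, T) at fixed offsets, so a 10–40 Hz band-pass
  isolates the QRS and 0.3–10 Hz the slow P/T components; ECG noise 0.05 mV
  (clinical chest leads are not cleaner in practice).
* **NIRS** — 48 columns (2 sensors × DC/AC/PD × 4 distances × 2
  wavelengths) on the NIRS clock including a configurable ppm skew. AC
  columns carry an asymmetric pulsation (sharp nadir at phase 0, slower
  recovery — so the sine correlation stays below 1 even without noise),
  amplitude 1 at the brain sensor and 0.3 at the muscle sensor, white noise
  SD 1 (pulsation SNR 1), plus a per-second random-walk drift interpolated
  to the sample grid (drift is sub-hertz by definition). PD and DC columns
  carry drift and noise but no pulsation.
* **Slow waves** — a Poisson candidate stream, rate-boosted by the mean von
  Mises acceptance `exp(−κ)I₀(κ)` and thinned by
  `exp(κ(cos(φ−φ₀)−1))`, yields onsets coupled to cardiac phase with
  concentration κ (κ = 0 gives exactly uniform phases; the realized rate
  matches `wave_rate_per_min` = 7.8/min up to refractory losses). The
  preferred phase corresponds to a 150 ms nadir→onset delay at the mean
  heart rate. Each wave is a piecewise half-sine template — brief leading
  positivity (0.3 s), negative lobe (0.4 s, raw depth 175 µV), rebound
  (0.5 s) — inserted into all six channels with ≤50 ms per-channel jitter
  and ±10% gain scatter. Two template choices deserve explanation. First,
  the leading positivity: the negative envelope of six noisy channels is
  itself negative nearly everywhere, so without a coherent positive
  excursion immediately before the wave the detected "onset" would be a
  noise-driven zero-crossing far from the planted time. Second, insertions
  are pre-shifted by the constant offset between the raw template onset and
  the downward zero-crossing the template exhibits after the canonical
  1–4 Hz filter — the onset *is defined on the filtered signal* in this
  analysis tradition, so the planted truth is expressed in the same
  landmark. The raw depth of 175 µV is chosen so the detected median
  amplitude on the filtered envelope lands near −105 µV, the scale reported
  for real overnight detections.
* **EEG background** — a spatially shared 0.5–4 Hz component (80% of the
  SD) plus independent 0.5–30 Hz channel noise (60%), total SD 15 µV. The
  shared delta term mimics the sub-threshold, spatially coherent delta
  activity of NREM sleep; it is what supplies the large candidate
  population the slope percentile needs (see above). Real sleep EEG
  additionally contains spindles, K-complexes, 1/f structure and
  non-stationarity that this generator does not emulate — passing tests
  here demonstrate the pipeline's internal correctness and calibration, not
  performance on clinical recordings.
* **Default coupling** — κ = 2. The strength of the real coupling is
  unknown (the tradition reports correlations well below ceiling), so the
  default is a moderate concentration; κ is a free parameter and the
  validation suite sweeps it (κ = 0 for calibration, κ = 8 for power).

A single RNG stream seeded from `config$seed` drives all draws;
`simulate_recording()` is byte-reproducible.

## Numerical choices

* Zero-crossing times are linearly interpolated between samples; slopes are
  first differences times the sampling rate.
* Overlapping accepted waves cannot arise (candidates are disjoint
  excursions), so no merge step is needed; the audit function re-checks
  every emitted wave against the landmark-ordering and criteria invariants.
* The bounded-lag search visits lags in order of increasing |lag| and keeps
  strictly greater correlations, which implements the smallest-|lag|
  tie-break without a tolerance.
* Zero-variance overlaps (constant traces) raise an error rather than
  returning NA.
* The per-trial detrend interacts mildly with pure oscillations: over a
  window covering a fractional number of oscillation periods the
  least-squares line of a sine is not exactly zero, so detrending a
  noiseless oscillation perturbs it slightly (worst case ~0.5% of the
  correlation in our checks). On real data the line removes drift that is
  orders of magnitude larger, so the trade is the right one; exactness
  checks of the correlation statistic therefore use drift-free signals
  without the (vacuous) detrend.
* The permutation engine processes surrogates in blocks of 100, using
  integer index matrices and a single detrend projection; with 500
  permutations and ~200 events a 30-minute night takes roughly one second
  for a NIRS pool.
* EDF storage quantizes to 16 bits over ±2000 µV (EEG) and ±6 mV (ECG):
  LSBs of 0.06 µV and 0.18 µV-equivalent, far below any threshold in play.

## Problem sizes in the validation suite

The statistical acceptance checks simulate 30-minute nights (~200 planted
waves): 200 uncoupled nights × 500 permutations for type-I calibration
(rejection rate at α = 0.05 inside the binomial band), 50 nights at κ = 8
for power and delay recovery (±50 ms), 20 nights for detection
recall/precision (≥0.9 at ±250 ms matching), 25 nights for the ECG band
dissociation (slow band significant, fast band not), and exact-oracle
equivalence checks on randomized small inputs. A two-hour night with
500 ppm clock skew verifies that trigger-based synchronization locates every
event within one NIRS sample while a skew-ignorant mapping drifts by
seconds.

## Group-level statistics

`run_group()` collects per-night correlations into a table and runs paired
t-tests between measures, Pearson correlations across nights, and — for the
four source-detector distances — a one-way repeated-measures ANOVA with
Greenhouse–Geisser sphericity correction (epsilon from the double-centered
covariance; fractional corrected degrees of freedom are reported). Identical
paired samples yield a documented NA t-statistic rather than a division by
zero.

## Known limitations

A second-order property of the permutation test deserves a warning. When
events are genuinely phase-locked to the cardiac cycle, *any* band of the
ECG whose variance is dominated by the QRS spikes acquires a 1 Hz-periodic
variance profile across the evoked window, even where the mean evoked
response is zero; the max-over-lags correlation can align the sine template
with that variance envelope, so the high-band (10–40 Hz) eERP test rejects
somewhat more often than its nominal level under coupling (~30% at
α = 0.05 in our synthetic nights, versus an exactly calibrated 5% when
coupling is absent). The directional dissociation — slow band strongly
locked, fast band mostly not — still holds, but the fast-band p-value
should not be read as a calibrated null under strong coupling with a clean
ECG; real recordings, where EMG and electrode noise dilute the QRS share of
the fast band, are less exposed.

* The generator's EEG lacks spindles/K-complexes and stage structure (the
  hypnogram is all-N3 by default); detection specificity against such
  transients is untested.
* The heart-artifact regression removal that some NIRS pipelines apply is
  deliberately absent — the pulsation *is* the signal of interest here.
* Manual wave editing is supported only as an external override list
  applied after detection; no interactive review exists.
* Surrogate latencies are restricted to the same stage mask as detection;
  whether a whole-night null is preferable is a judgment call, and the mask
  choice is configurable through the allowed-times argument.
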