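# pulsewave

Are individual sleep slow waves phase-locked to the heart beat? Frequency-
domain NIRS recordings carry a prominent cardiac pulsation — light
absorption rises with every arterial pressure wave — and the same rhythm is
trivially present in the ECG. `pulsewave` implements a complete single-night
analysis that asks whether the *onsets* of detected slow waves occur at a
preferred phase of that pulsation, for researchers working with simultaneous
polysomnography (EEG + ECG) and NIRS.

The pipeline, stage by stage:

1. **Slow-wave detection** on the *canonical wave* — the negative envelope
   (pointwise minimum) of six EEG channels (F3, F4, C3, C4, O1, O2)
   band-passed 1–4 Hz with a zero-phase filter. A negative half-wave is a
   slow wave when its peak is 5 robust SDs below the median negative
   activity, its duration lies in 250–1250 ms, its rising slope reaches the
   within-night 90th percentile, and at least one individual channel
   co-expresses it (r ≥ 0.9 within ±100 ms).
2. **Heart rate** from an energy-based R-peak detector; the mean N3 rate
   `f` defines the reference oscillation.
3. **Evoked responses**: the raw NIRS (nERP) or ECG (eERP) signal is cut
   into ±3 s epochs around each wave onset (NIRS events mapped through the
   trigger-based clock synchronization), each trial linearly detrended, and
   averaged. No other preprocessing touches the NIRS data.
4. **Phase-locking statistic**: the Pearson correlation between the evoked
   trace and the template `s(t) = −cos(2π f t)` (nadir at the event),
   maximized over lags within half a template period. The lag at the
   maximum is the *phase delay* from pulsation nadir to wave onset.
5. **Permutation test**: the identical statistic recomputed for thousands
   of surrogate event sets drawn at random latencies from the same sleep
   stages; `p` is the proportion of surrogate correlations ≥ the observed
   one.

A synthetic-data module (`simulate_recording()`) generates complete
EEG/ECG/NIRS nights — quasi-periodic cardiac cycle, P-QRS-T morphology,
asymmetric NIRS pulsation on a clock with configurable ppm skew, and planted
slow waves whose onsets are von Mises-coupled to cardiac phase — with full
ground truth, so every stage is testable without clinical data.

## Worked example

Simulate a 30-minute coupled night and run the full analysis:

```r
library(pulsewave)

night <- run_night(list(
  sim   = list(duration_s = 1800, coupling_phase_delay_s = 0.15, seed = 11),
  stats = list(pools = c("brain_ac", "muscle_ac", "brain_pd", "ecg"),
               n_perm = 500, seed = 5)))
night
```

```
<night_result> 222 waves (7.4/min, median -115.1 uV), HR 60.0 bpm
  brain_ac.onset         r =  0.982  delay =   119 ms  p = 0
  muscle_ac.onset        r =  0.944  delay =   119 ms  p = 0
  brain_pd.onset         r =  0.080  delay =    24 ms  p = 0.54
  ecg.onset              r =  0.929  delay =   465 ms  p = 0
```

Reading the output: 222 slow waves were detected (7.4/min over N2+N3,
median filtered amplitude −115 µV). The brain-sensor AC pool shows a strong
oscillatory evoked response at the heart-rate frequency (r = 0.98) whose
nadir precedes the wave onset by ~119 ms — close to the planted 150 ms
coupling delay — and none of 500 random-latency surrogates reached the
observed correlation (p = 0). The photon phase-delay (PD) pool, which
carries no pulsation, is indistinguishable from its null (p = 0.54), and
the muscle-sensor control shows the same oscillation at reduced amplitude.
`plot(night$phase_lock$brain_ac.onset)` draws the null histogram with the
observed correlation marked; `report(night, "night.md")` writes the summary
table.

Group-level plumbing (`run_group()`) compares measures across nights with
paired t-tests, cross-measure Pearson correlations, and a Greenhouse–
Geisser-corrected repeated-measures ANOVA across source-detector distances.

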