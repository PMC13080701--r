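---
title: "Heartbeat-evoked potentials around seizures and syncope: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heartbeat-evoked potentials around seizures and syncope: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hepline)
```

## The measurement

The heartbeat evoked potential (HEP) is the scalp EEG response time-locked
to the heartbeat: average enough EEG segments anchored on ECG R waves and
the stimulus-unrelated background cancels, leaving a small potential that
indexes cortical processing of cardiac afferent signals. `hepline`
implements one specific, fully parameterized HEP pipeline and exercises it
end to end on synthetic polygraphy with known ground truth.

The derivation, per analysis segment:

1. **R-peak anchoring.** R waves are detected on the raw ECG lead with a
   Pan–Tompkins-style detector (derivative → squaring → 120 ms moving
   integration → adaptive threshold at 20 % of the 99th percentile →
   250 ms refractory period), each detection refined to the raw-signal
   extremum within ±50 ms, with automatic polarity handling. On clean
   synthetic ECG the detector is exact to one sample, which is the contract
   the tests enforce; no claim is made about pathological rhythms.
2. **Epoching.** One epoch per R wave, −0.400 s to +0.800 s (307 samples at
   256 Hz). A beat is usable only if the interval to the *next* R wave is
   at least 700 ms — a shorter interval would put the following QRS complex
   inside the epoch and contaminate the average with cardiac field
   artifact. Epochs that would cross the segment bounds are dropped and
   counted separately.
3. **Amplitude rejection.** An epoch is rejected if its within-epoch
   peak-to-peak range strictly exceeds 100 µV on any analysis channel
   (a `max_abs` variant is available behind a flag; peak-to-peak is the
   default reading of "maximum potential difference").
4. **Back-averaging and baseline.** Sample-wise mean over the surviving
   epochs, then per-channel subtraction of the mean over −0.350 to
   −0.100 s pre-R. An average built from fewer than 60 usable epochs is
   flagged invalid and excluded from all downstream summaries.
5. **Amplitude.** The per-channel HEP amplitude is the mean of the
   corrected average over +0.455 to +0.595 s post-R; the **compound HEP**
   is the sum of the C4 and F8 amplitudes, the two leads carried forward
   to inference (this keeps the multiple-comparison burden at one value
   per segment).

Windows specified in seconds are converted to samples by rounding to the
nearest sample: epoch and baseline windows are half-open
`[round(t0*fs), round(t1*fs))`, while the measurement window includes both
endpoint samples after rounding. All window arithmetic works at any
integer sampling rate, not just the 256 Hz the recordings use.

## Study arms and segmentation

**Seizure arm.** Annotations pair each seizure onset and offset (events
shorter than 5 s are excluded; events with mixed or unclassifiable
semiology are dropped with a logged count). Each event contributes a
preictal window `[onset − 300 s, onset)` truncated at the recording start
and at the previous event's offset, and a postictal window
`[offset, offset + 300 s)` truncated symmetrically. The interictal
reference is the longest annotated artifact-free wakeful interval of at
least 5 min (ties broken by earliest onset); a recording without one is
flagged and excluded from change analyses. Per event, the outcome is the
compound-HEP change (preictal − interictal); events are averaged within
subject for each seizure-type × semiology combination so a subject
contributes at most one value per comparison, avoiding pseudoreplication.
The heart-rate-change covariate is computed on exactly the same segments.

**Tilt-table arm.** Symptom-report annotations carry a category (cardiac,
respiratory, abdominal, cephalic, peripheral, psychological). The
pre-symptom condition is the 2 min ending at each report, with overlapping
same-category windows merged; the baseline is every interval lying more
than 2 min before *every* report of that category (per-category exclusion
by default; a flag switches to excluding all categories' windows).
Because tilt-table heart rates are high and windows short, per-subject
condition values use a within-subject bootstrap: the available beat epochs
are resampled with replacement 20 times, the compound HEP of each
resample's average is computed, and the mean of the 20 values is the
subject's condition estimate. Epochs are put in canonical (anchor-time)
order before resampling, and resample draws are made in that rank space,
so the estimate is invariant — bit for bit — to the order epochs arrive in.

## Inference

Subject-level values more than 3 SD from their comparison group's mean are
excluded in a single pass using the full sample's mean and SD. A
consequence worth knowing: the largest attainable |z| in a sample of n is
(n−1)/√n, so this rule cannot remove anything from groups of ten or fewer
— exclusion only bites at realistic cohort sizes.

- **Per-cell one-sample tests** of mean HEP change against zero and the
  **planned two-sample contrasts** (FS vs ES within semiology, motile vs
  non-motile within aetiology) use subject-level bootstrapped two-tailed
  t-tests: values are re-centered to the null (each group to its own
  mean), subjects are resampled with replacement within their group 2000
  times, and the empirical p-value is the +1-smoothed two-tailed tail
  proportion `(1 + #{|T*| ≥ |T_obs|}) / (B + 1)`. The Welch statistic is
  used for the two-sample case. Significance is judged on the empirical
  p-value at Bonferroni-corrected alpha 0.05/4 = 0.0125 for the four
  planned comparisons.
- **ANCOVA.** Within each aetiology, OLS of HEP change on semiology with
  heart-rate change as covariate; term F statistics use type-II sums of
  squares (robust to unbalanced cells). The bootstrapped F imposes the
  null by centering the outcome within the tested term's levels, then
  case-resamples within strata — the +1-smoothed upper tail of the
  resampled F is the empirical p. (Null-centering is needed for a valid
  reference distribution; plain case resampling reproduces the observed
  effect and has no power interpretation.)
- **Tilt arm.** Classical paired t-tests (pre-symptom vs baseline within
  subjects) per group × category at alpha 0.05/6 ≈ 0.0083 for the six
  symptom categories. A degenerate zero-variance nonzero difference is
  flagged and treated as significant; identically zero differences give
  t = 0, p = 1.

Every stochastic step takes a seed derived from the master seed and a
stable identifier (subject id, test name) via a small FNV-1a hash, so
adding a subject to a cohort never perturbs any other subject's stream and
a full re-run with the same configuration reproduces every number
bit-identically.

## The synthetic-data generator

The generator emulates the *structure* of clinical polygraphy, not its
biophysics:

- **ECG**: a Gaussian R deflection (with small Q/S dips and a T bump) at
  beats whose R-R intervals combine a slow AR(1) heart-rate drift
  (SD 2 bpm) with white jitter (SD 25 ms), truncated at 300 ms.
- **EEG**: white Gaussian background (default SD 10 µV) on all ten
  channels of the minimum montage.
- **Heartbeat-locked component**: a raised cosine supported on
  0.44–0.62 s post-R on C4 and F8, scaled so its mean over the sampled
  measurement window equals the target amplitude *exactly* (the
  ground-truth table is exact before noise). The support keeps the
  component clear of the QRS window and — at resting rates — of the next
  beat's baseline window.
- **Artifacts**: 0.2 s boxcar transients (> 100 µV) on random channels as
  a Poisson process.
- **Annotations**: interictal marks, seizure onset/offset pairs with type
  and semiology, or symptom reports with categories, serialized as EDF+
  time-stamped annotation lists.

Cohorts draw each subject's resting HEP level and their condition shift
independently from normal distributions around the cell means
(`between_subject_sd_uv` each, default 1 µV), so subject-level inference
faces genuine between-subject variance in both level and effect.

**A periodicity confound the generator reproduces.** Because the response
recurs every beat, each beat's component sits `RR − 0.62` to `RR − 0.44` s
*before the next* R wave. Once RR drops below ~0.97 s the pre-R baseline
window (0.35–0.1 s) overlaps the previous beat's response and baseline
correction subtracts part of it. Two consequences: (i) at tilt-table heart
rates (75 bpm) the measured pre-symptom shift is attenuated by roughly
half relative to the injected value, identically in both conditions, so
directions and tests are unaffected; (ii) a *peri-ictal heart-rate change*
makes the overlap differ between preictal and interictal segments and
masquerades as a HEP change even with no injected shift —
`analysis/04_hr_confound.R` demonstrates this and shows the ANCOVA's
heart-rate covariate absorbing it. Real HEPs share this geometry; it is
why the default seizure cells use matched heart rates (the confound is a
configuration away, not a default), and why heart-rate change is a
covariate rather than an afterthought. For the same reason the seizure-arm
default heart rate is 60 bpm, where the baseline window is clear of the
previous beat's response.

What the generator does **not** emulate: realistic EEG spectra
(1/f background, alpha rhythm), volume conduction of the cardiac field
beyond an optional R-locked bleed term, ectopic beats, electrode pops, or
drifting electrode impedances. Passing tests therefore demonstrate that
the pipeline's arithmetic, gating, and inference behave as specified —
not that the detector or ASR would perform equally on pathological
clinical signal.

## Numerical and implementation choices

- **Zero-phase filtering.** The 0.53–70 Hz band-pass applies the squared
  magnitude of 4th-order digital Butterworth designs in the frequency
  domain (reflect-padded FFT) — exactly the magnitude a forward–backward
  `filtfilt` pass realizes, without its edge transients, and zero-phase so
  component latencies are untouched. Design cutoffs are pre-warped (in tan
  space, by `0.414^(1/8)`) so the *combined* two-pass response is −3 dB at
  the nominal band edges. A time-domain `filtfilt` of the same designs
  serves as an independent oracle in the tests. The ECG lead is never
  filtered; beats and HRV always come from the raw ECG.
- **Artifact subspace reconstruction.** Calibration is the quietest
  contiguous 60 s of EEG (or an explicit interval). In each half-
  overlapping 0.5 s window the data are decomposed into their principal
  directions; a component whose RMS exceeds `cutoff` (default 20) times
  the calibration SD along that same direction is zeroed before
  reconstruction; each sample takes its value from the window whose center
  is nearest. Windows whose total energy cannot arithmetically flag any
  component (a trace bound against the smallest calibration eigenvalue)
  are passed through unchanged, which is also what the full decomposition
  would do. Clean data pass through exactly; `cutoff → ∞` is the identity;
  the ECG is never altered.
- **HRV.** RMSSD is the primary metric; LF (0.04–0.15 Hz) and HF
  (0.15–0.40 Hz) powers come from a Hann/Welch periodogram (64 s segments,
  50 % overlap) of the R-R tachogram cubic-spline-resampled at 4 Hz, and
  are `NA` below 2 min of beats. Mean heart rate is `60000 / mean(RR ms)`.
- **Rejection accounting order.** The R-R gate is applied before the
  amplitude gate, so the counts `total = used + RR-rejected +
  bounds-dropped + amplitude-rejected` are well defined and reproducible;
  the audit log reconciles them for every segment.
- **Ties and degenerate inputs.** Epoch averages are computed in canonical
  anchor-time order (order-invariance is bit-exact); R-R threshold
  comparisons carry a 1 ns tolerance so intervals exactly at 700 ms
  survive floating-point differencing; a constant outcome in the ANCOVA
  reports F = 0, p = 1 rather than 0/0; SD-zero samples exclude no
  outliers.
- **Compiled kernels.** Epoch gathering, per-epoch extrema, beat-template
  accumulation and the generator's Gaussian noise stream (xoshiro256++
  with Box–Muller, seeded from the configuration seed) are C++ for speed;
  all window arithmetic stays in R.

## Problem sizes in the bundled studies

The analysis scripts and the acceptance checks run cohorts of 15
subjects/cell (seizure arm, four cells) and 19 subjects/group (tilt arm),
matching the effect-recovery conditions stated with the package's
acceptance properties. Seizure-arm recordings in the multi-seed recovery
studies keep the full 5-min interictal and preictal windows but only 65 s
after seizure offset, since the postictal role is not among those studies'
outcomes, and those studies skip preprocessing: the suite separately
verifies that band-pass + ASR change clean-data HEP amplitudes by less
than 0.1 µV, so the omission is measurement-neutral and the studies run in
a fraction of the time. The single-seed demonstration scripts
(`analysis/02`, `03`) run the full preprocessing chain. The directional-
recovery property uses 50 seeded replicate studies for the seizure arm and
20 for the tilt arm; bootstrap calibration uses 2000 null simulations at
2000 resamples each.

## Known limitations

- The EDF+ writer emits one fixed layout (1 s records, symmetric physical
  ranges, annotations in their onset record); the reader handles that
  layout plus common label dialects, but not every EDF variant in the
  wild (discontinuous EDF+D files, per-signal sampling rates other than a
  shared one, sub-second record durations).
- ASR here reconstructs by zeroing flagged window-PCA components against
  calibration variances; it is a deliberately small variant of the
  published method (no Riemannian statistics, no sliding covariance
  blending), pinned by passthrough/suppression/identity contracts rather
  than by equivalence to any reference implementation.
- The 3-SD outlier rule, applied per comparison group, cannot fire at
  n ≤ 10 (see above) — this is a property of the rule, not a bug, and is
  tested as such.
- Between-subject SD applies to both level and shift; no subject-level
  correlation structure (e.g., level–shift correlation) is modelled.
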