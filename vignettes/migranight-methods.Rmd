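---
title: "Detecting pre-migraine nights from wrist-sensor sleep data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting pre-migraine nights from wrist-sensor sleep data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(migranight)
```

## The problem

Migraine attacks are often preceded by a pre-ictal phase in which autonomic
physiology already differs from baseline. If that signature is measurable
during the night before an attack, a wrist-worn device could warn the user
on waking, in time for preventive medication. `migranight` implements a
complete analysis pipeline for this question: ingest multi-rate wrist
recordings (Empatica E4 export dialect), keep only the sleep interval of
each night, summarize every night as a 110-feature vector, expand the small
imbalanced night set into pairwise *night-comparison* observations, train
regularized discriminant classifiers with noise-injected forward feature
selection, and evaluate with protocols that respect the provenance of every
derived observation.

Only sleep-time data are analysed. Daytime wrist photoplethysmography is
dominated by motion artifact, so the pipeline never attempts to use it;
sleep is located automatically from the accelerometer.

## Signals and preprocessing

The device records six channels: 3-axis acceleration (32 Hz, raw units of
1/64 g), blood volume pulse (64 Hz, arbitrary units), electrodermal
activity (4 Hz, µS), skin temperature (4 Hz, °C), heart rate (1 Hz, bpm)
and an irregular list of inter-beat intervals (seconds). Acceleration is
reduced to its Euclidean magnitude in g. All channels are brought to the
rate of the fastest channel (64 Hz) on the intersection of their time
spans, which makes inter-signal correlations well-defined. Up-sampling of
the slow regular channels uses zero-order hold: a 1–4 Hz signal carries no
intra-sample structure, and sample-and-hold does not invent any; it also
preserves the mean of a constant signal exactly. Only the irregular
inter-beat events are linearly interpolated onto the grid
(`ibi_interp`); the raw event list is carried alongside for the HRV
features.

**Sleep detection.** The sleep interval is the longest contiguous run in
which the rolling standard deviation of the acceleration magnitude
(window 60 s) stays below 0.01 g, with movement gaps shorter than 5 min
bridged (brief arousals do not end a night) and a minimum duration
(default 3 h). These are conventional actigraphy-style values and all are
configurable via `sleep_params()`. On synthetic nights the detected
boundaries fall within seconds of the generator's ground truth; the
features are computed over windows of hours, so residual boundary error of
even minutes is immaterial. A night with no qualifying quiet interval is
dropped with a warning rather than guessed at.

**Labelling.** A night is keyed to the day the subject wakes into: if the
diary flags that calendar day as a migraine day, the night is
`pre_migraine`, otherwise `non_migraine`. This matches the intended use
(a warning on waking). Calendar-day assignment uses a configurable
timezone offset (default UTC), since exports carry POSIX timestamps.

## The 110-feature nightly vector

Each night yields exactly 110 named features, in a fixed registry order
(`feature_registry()`):

* **Full-night statistics (46).** SD and mean of {acc magnitude, BVP,
  temperature, HR, EDA, inter-beat intervals}; minimum of {acc, BVP,
  temperature, HR}; maximum, median and the 5th/25th/75th/95th percentiles
  of {acc, BVP, temperature, HR, EDA}. The EDA minimum is excluded
  everywhere: wrist skin conductance rests at its floor, so its minimum is
  uninformative. Percentiles interpolate linearly between order
  statistics.
* **Quarter-comparison features (44).** The sleep interval is cut into
  four equal parts by sample count (⌊N/4⌋ per quarter, remainder
  truncated) and, for the same statistic/signal combinations (without the
  interval series), the feature is *last quarter − first quarter*. The
  last quarter is the closest to the following day's potential attack, so
  a within-night trend shows up here. The sign convention (last minus
  first) is fixed for reproducibility; discriminant classifiers are
  indifferent to it.
* **Inter-signal correlations (14).** Pearson correlations of all 15
  unordered pairs of the six resampled columns, minus the (HR,
  `ibi_interp`) pair: heart rate is a deterministic transform of the
  inter-beat series, so that correlation is ≈ −1 by construction and
  carries no information. A zero-variance column yields correlation 0
  rather than NA, keeping every vector finite.
* **Time-domain HRV summaries (6).** RMSSD, mean and SD of successive
  inter-beat differences, beat count, NN50 (successive differences
  exceeding 50 ms) and total spectral power of the interval series. Total
  power uses a Welch estimate (mean modified periodogram over
  50 %-overlapping Hann segments) of the interval series linearly
  resampled to 4 Hz, summed over 0–2 Hz; method and band are arguments.
  With fewer than three intervals the difference-based features are
  reported as 0 with a warning, the beat count stays exact.

Where a summary row mentions "HRV" as a signal (the SD and mean rows), it
is computed on the raw inter-beat interval series — only the irregular
interval data carry heart-rate variability; the interpolated 64 Hz column
exists for the correlation block.

## Night-comparison augmentation

A subject contributes a few dozen nights, few of them pre-migraine —
too few and too imbalanced to train on nights directly. The augmentation
turns `a` pre-migraine and `b` non-migraine nightly vectors into
`a·b + b(b−1)/2` labelled difference observations:

* every (pre-migraine `m`, non-migraine `n`) pair yields `m − n`,
  labelled a migraine comparison;
* every unordered pair of non-migraine nights yields `s · (nᵢ − nⱼ)` with
  `s` drawn uniformly from {+1, −1}, labelled a non-migraine comparison.

Each unordered pair is used once — emitting both directions would
duplicate the same information with flipped sign — and the random sign
prevents the classifier from keying on an arbitrary orientation.
Pre-migraine nights are never differenced against each other (consistent
with the count formula). Pairs are ordered lexicographically by night id
before the sign draws, so the map from seed to matrix is deterministic.
Because the sign draws make the matrix stochastic, every evaluation is
repeated with fresh matrices (20 repetitions by default) and reported as
mean ± SD.

For a 17 pre-migraine / 12 non-migraine subject this yields
`r count_observations(17, 12)` observations; for 14/21,
`r count_observations(14, 21)`.

## Classification

`fit_discriminant()` implements Gaussian discriminant analysis with class
score

$$\delta_c(x) = -\tfrac12 \log|\Sigma_c|
  - \tfrac12 (x-\mu_c)^\top \Sigma_c^{-1} (x-\mu_c) + \log \pi_c,$$

with a covariance shared across classes (LDA, linear boundary) or
per-class (QDA, quadratic boundary). Difference features can be collinear,
so every covariance receives a relative ridge
`λ·(trace(S)/d)·I` (default λ = 10⁻⁶). Priors are empirical class
frequencies (the comparison classes are imbalanced by construction). Exact
score ties resolve deterministically to the non-migraine class. The
trace-relative ridge is not equivariant under rescaling a single feature;
at the default λ the effect is negligible, and the scale-invariance
property of the fit→predict pipeline is verified in the small-λ regime.

**Feature selection.** Sequential forward selection: starting from the
empty set, repeatedly add the feature that maximizes validation balanced
accuracy of the refitted model; stop when the best improvement is below
ε = 0.001 or 15 features are reached. Validation balanced accuracy is
coarse on small folds and exact ties between candidates are common; ties
resolve to the earliest feature in registry order. (Breaking ties by
training accuracy was evaluated and rejected: it rewards exactly the
selection-stage overfitting the noise injection is meant to damp, and
measurably degrades null calibration.) To blunt selection-stage
overfitting, the
training set is augmented during the search with one noisy copy of itself
(per-feature Gaussian noise at 0.1 × the feature's SD). The final model is
refit on the un-noised train+validation data with the selected features;
refitting on the noisy set instead is available as a flag, since either
reading of the protocol is defensible.

## Evaluation protocol

**Personal models.** Per subject and repetition: two pre-migraine nights
are drawn and *all* comparisons built from them form the migraine side of
the test set — so no pre-migraine night is ever shared between training
and test — plus a random 20 % (rounded, minimum 1) of the non-migraine
comparisons. The remainder is split into five observation-level folds,
four for training and one for validating the feature search. A machine
check (`check_no_leakage()`) enforces the migraine-night invariant on
every split. Two residual overlaps are accepted deliberately, because the
protocol defines them that way: test migraine comparisons involve
non-migraine nights that also appear inside training comparisons, and test
non-migraine comparisons may share a member night with training ones.

**User-independent models.** Leave-one-subject-out: the held-out subject's
comparisons are the test set; the other subjects' pooled comparisons form
the five folds.

**Night-level aggregation.** Test predictions are mapped back to nights:
a migraine comparison votes for its left (pre-migraine) night; a
non-migraine comparison votes for both member nights; a prediction of
"migraine comparison" is a pre-migraine vote. The night's label is the
modal vote, ties going to pre-migraine (an alert-favoring rule: for a
warning system the cheaper error is a false alert). Nights receiving no
test votes are excluded. Balanced accuracy is the mean of the two
night-level true positive rates; sensitivity is reported as the TPR of
non-migraine nights and specificity as the TPR of pre-migraine nights,
the orientation in which these models tend to recognize non-migraine
nights more reliably.

## The synthetic cohort generator

No public dataset exists for this problem, so the package ships a seeded
generator (`generate_night()`, `generate_subject_dataset()`) that emulates
per-subject multi-day recordings: an evening-to-morning session with
high-movement wake padding, a quiet sleep interval with Poisson movement
arousals, an AR(1) inter-beat process (coefficient 0.9, configurable)
whose successive-difference SD realizes the night's RMSSD target, heart
rate as 60 over a rolling 10-beat interval mean, a pulse waveform built
from the beat sequence at 64 Hz, and temperature/EDA as night-level draws
plus slow drift and sensor noise. Whole nights go missing with a
configurable probability (device off while charging or in water); partial
gaps are not simulated. Samples are rounded to the export dialect's six
decimals, so generated sessions round-trip bit-exactly through the CSV
writer.

Pre-migraine nights receive configurable shifts, each expressed in
multiples of the subject's *between-night* SD of that quantity
(`effect_spec()`): by default temperature +1 SD, EDA +1 SD, HR +0.5 SD,
RMSSD −1 SD, movement +0.5 SD, plus an optional within-night trend term.
These magnitudes are free parameters of the calibration experiments, not
claims about migraine physiology — no quantitative pre-ictal effect sizes
exist to copy. A zero effect makes the two night classes identically
distributed by construction, which is what the null-calibration tests
exploit.

What the generator does *not* emulate: real sensor artifacts and dropout
within a night, sleep architecture (stages, mid-night waking), circadian
structure beyond a nightly drift, inter-night autocorrelation of
physiology, and attack-day (as opposed to pre-attack) dynamics. Passing
tests on synthetic cohorts therefore demonstrate that the pipeline
recovers signals of a stated size under its own assumptions — not that
real pre-migraine nights carry such signals.

## Problem sizes and numerical choices

The test suite and calibration experiments run on scaled-down cohorts:
7 subjects × 28 diary days with ~20-minute sleep intervals at the full
native sampling rates, chosen so the complete synthetic study (three
cohorts, personal and user-independent evaluation, 20 repetitions each)
runs on a single CPU in minutes. Short nights are acceptable because the
class signal lives in between-night variation; night length mainly
affects within-night estimation noise, which enters the nightly summaries
only weakly relative to the between-night SDs the effects are expressed
in.

Other numerical choices: quarters by sample count with truncation;
percentile interpolation type 7 (R default); correlation of a
zero-variance column defined as 0; per-repetition seeds derived from the
master seed by a seeded draw, keeping every run reproducible end to end.

## Calibration results and known limitations

Three properties are exercised end to end on generated cohorts:

* **Null calibration.** With zero effect, personal QDA balanced accuracy
  should sit at chance. In practice it centers slightly *above* 0.5
  (≈ 0.55 on average, with subject-level scatter of about ±0.05). This is
  not an implementation artifact: migraine comparisons are always oriented
  (pre-migraine minus non-migraine) and share their non-migraine side with
  training comparisons, so a small part of the selection-stage overfit
  transfers to held-out migraine nights; the alert-favoring tie rule adds
  a further nudge. Observation-level analysis shows the two per-class
  recognition rates summing to ≈ 1.1 under the null. Users interpreting
  personal-model accuracies near 0.6 should treat them as consistent with
  no signal.
* **Signal recovery.** With every channel shifted by 2 between-night SDs,
  personal QDA reaches a mean balanced accuracy of ≈ 0.82 across
  subjects. An oracle variant that skips feature selection and uses the
  four truly shifted summary features reaches ≈ 0.89 on the same cohort
  and split protocol — the gap is the cost of wrapper selection on small
  validation folds, not of the classifier or the aggregation.
* **Personal vs. user-independent.** When effect directions differ
  between subjects, leave-one-subject-out accuracy collapses toward
  chance while personal models are unaffected (difference ≈ 0.25),
  reproducing the qualitative finding that pre-ictal signatures are
  personal.

Further limitations: the discriminant models assume Gaussian class
conditionals, which difference features only approximate; the sleep
detector returns one interval per session (naps are ignored); nights
waking into days without a diary entry are dropped, not imputed; and with
fewer than three pre-migraine nights a subject's personal split is
reported as not evaluable rather than silently merged.
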