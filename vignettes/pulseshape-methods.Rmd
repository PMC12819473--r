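---
title: "Methods: pulse morphology and the Pulse Shape Index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pulse morphology and the Pulse Shape Index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulseshape)
```

## Overview

`pulseshape` implements a morphological analysis of cardiac pulse waveforms
in continuous intracranial-pressure (ICP) and noninvasive skull-expansion
recordings. The pipeline has four stages:

1. **Segmentation** — locate the diastolic trough that starts each beat.
2. **Morphology** — normalize each beat, resample it to a uniform length,
   designate the P1/P2/P3 peaks, and classify the configuration into one of
   four shape classes (with artifact screening).
3. **Pulse Shape Index (PSI)** — summarize class fractions over 10-second
   windows: `PSI = sum(i * p_i)`, ranging from 1 (all class 1, dominant
   percussion wave) to 4 (all class 4, single rounded peak).
4. **Statistics** — method agreement between the two channels
   (Bland–Altman, Lin's CCC, Spearman) and nonparametric group comparisons
   (Kruskal–Wallis with Dunn post hoc tests, Wilcoxon signed-rank,
   Scheirer–Ray–Hare rank factorial with partial eta-squared).

Because no clinical recordings ship with the package, a seeded synthetic
cohort generator produces paired signals with ground-truth onsets and class
labels, making every stage testable end to end.

## The four morphological classes

Each beat is classified from the amplitudes `A1, A2, A3` of its designated
P1/P2/P3 peaks (an absent peak contributes amplitude 0), with rules applied
in order:

| class | rule | interpretation |
|-------|------|----------------|
| 4 | fewer than two designated peaks | single rounded/triangular pulse |
| 1 | `A1 >= A2` and `A1 >= A3` | dominant percussion wave (normal) |
| 2 | `A2 >= A1` and `A1 > A3` | prominent tidal wave |
| 3 | `A2 > A1` and `A3 >= A1` | P2 and P3 dominate P1 |

Residual configurations (e.g. `A3 > A1 >= A2`) are resolved by priority of
rule 3 over rule 2 and flagged via the `ambiguous` attribute so their
frequency can be audited; on generator output they are rare (< 1%).

```{r rules}
p <- resample_pulse(normalize_pulse(pulse_template(2, 160, noise_sd = 0)))
classify_pulse(find_pulse_peaks(p))
```

## Segmentation: multiscale trough detection

`detect_onsets()` applies automatic multiscale peak detection to the negated,
detrended signal. A local-minima scalogram is computed for window scales
`k = 1..L`; the scale minimizing the count of non-minima is selected, and
samples that are minima at *every* scale up to it become onsets. The scale
cap `L = fs * 60 / min_bpm / 2` (half the longest plausible beat) keeps the
search physiological, and a spacing filter merges onsets closer than the
fastest plausible beat (`60 / max_bpm` s), keeping the deeper trough.

Numerical choices:

* **Detrending** subtracts a 10-s sliding local mean so slow pressure shifts
  (e.g. a compression plateau) do not bias the scalogram. The running mean is
  computed with a cumulative-sum formulation (O(n), shrinking windows at the
  edges).
* Detection is invariant to adding constants and to positive rescaling, so
  the same code serves the mm Hg pressure channel and the arbitrary-unit
  expansion channel.
* Beats are cut half-open, `[onset_i, onset_{i+1})`, so consecutive segments
  tile the signal with no gaps or overlaps.

## Morphology: normalize, resample, designate, classify

Each segment is min–max normalized to `[0, 1]` (removing amplitude
information, which is irrelevant to shape class) and linearly resampled to
**180 samples** (removing heart-rate-driven length differences). Linear
interpolation is used deliberately: it preserves endpoints exactly and cannot
overshoot, so resampling can never fabricate a peak.

Peaks are local maxima of a lightly smoothed copy (5-sample moving average)
with topographic prominence of at least 0.02 on the normalized scale; they
are designated P1/P2/P3 by latency windows `[0.02, 0.30)`, `[0.30, 0.55)`,
`[0.55, 0.90)` of the pulse duration (the highest peak wins within a
window). Peak amplitudes are read from the unsmoothed pulse so smoothing
never distorts the rule comparisons.

Artifact screening uses enumerated reason codes: `DURATION` (beat length
outside `[60/max_bpm, 60/min_bpm]` s), `FLAT` (degenerate range),
`BASELINE_JUMP` (onset-to-end jump above half the pulse amplitude),
`OSCILLATORY` (more than 6 prominent maxima), `SHAPE_OUTLIER` (mean absolute
deviation above 0.35 from the pointwise median of up to 10 neighboring valid
pulses), plus `SHORT_WINDOW` for PSI windows with too few valid pulses.

A retrainable multinomial-logistic surrogate
(`train_surrogate_classifier()`) stands in for heavier learned classifiers;
the deterministic rules above remain the pipeline's classifier of record.

## PSI windows

`psi_windows()` tiles each protocol phase with non-overlapping 10-s windows
anchored at the phase start, dropping a trailing partial window. Artifact
pulses are counted but excluded from the class fractions. A window needs at
least `min_pulses = 5` valid pulses for a defined PSI — at plausible heart
rates a 10-s window holds 7–30 beats, so 5 tolerates a couple of artifacts
without letting two beats determine an index value. Per patient and phase,
windows are reduced by the **median** (IQR reported alongside), consistent
with the nonparametric statistics downstream.

## Synthetic generator

A pulse is the sum of three Gaussian bumps (P1, P2, P3) on a linearly
declining diastolic baseline:

* latencies `(0.15, 0.40, 0.65)` of the beat, widths `(0.07, 0.10, 0.12)`
  interpreted as full width at half maximum (FWHM; divided by 2.355 to get
  Gaussian standard deviations) — the natural "visual width" of a wave on a
  tracing;
* canonical amplitude triples per class: class 1 `(1.0, 0.7, 0.4)`, class 2
  `(0.8, 1.0, 0.5)`, class 3 `(0.6, 1.0, 0.8)`, each jittered per beat
  (sd 0.02) under the constraint that the triple still satisfies its class
  rule;
* class 4 is a smooth beta-shaped bump `t^1.636 (1 - t)^2` peaking at 0.45
  of the beat — a "rounded or triangular" single-peak pulse that vanishes at
  both beat boundaries;
* the baseline declines **linearly** to zero across the beat. An exponential
  tail was rejected: its flat end made the inter-beat trough drift under
  respiratory modulation, which is a property of the toy signal rather than
  of real pulses, and it biased onset detection.

Patient recordings concatenate per-beat templates (per-beat heart rate drawn
from the patient's distribution), scale the pressure pulse to 4 mm Hg, add
0.5 mm Hg respiratory modulation at 0.25 Hz, and place the result on a
baseline that follows a logistic plateau (5-s ramps) from the baseline level
to the compression level. The pulsatile component is mean-centered within
each phase so phase means track the configured pressure levels exactly. The
expansion channel reuses each beat's class (shifted with a configurable
disagreement probability), has no absolute baseline, and is zero-mean.

Cohort defaults: groups of 17 intact-skull, 17 craniotomy/fracture and 13
craniectomy patients; baseline class mixtures `(0.3, 0.5, 0.1, 0.1)`
(expected class 2.0) for the first two groups and `(0, 0.1, 0.3, 0.6)`
(expected class 3.5) for craniectomy; craniectomy expansion-channel classes
shift one class down with probability 0.5 (expected class 3.0), modeling the
noninvasive channel underestimating morphology after bone removal; baseline
pressure `N(11.8, 1.5)` mm Hg with a compression rise of `N(5.3, 0.8)`;
2% artifact beats and 2% additive noise. Ages are uniform on 18–78 and shift
each patient's mixture upward via `shift_mixture()` with strength
`age_kappa = 0.6`, **centered at the mid-age (48 years)** so the age drift
does not move the group calibration targets; the resulting population
Spearman correlation between age and PSI is about 0.35.

All cohort randomness flows from a single seed; per-patient sub-seeds are
drawn once up front, so runs are reproducible and patients are independent.

Known limits of realism: no slow ICP B-waves, no heart-rate–pressure
coupling, stationary mixtures within a phase, and artifact shapes
(random-walk or clipped half-pulse) chosen for screen-ability rather than
fidelity.

## Statistics

* **Bland–Altman**: bias, `bias ± 1.96 sd` limits, percent outside.
* **Lin's CCC** with population (n-denominator) moments:
  `2 cov / (var_x + var_y + (mean_x - mean_y)^2)`.
* **Spearman**: Pearson correlation of mid-ranks; p from the t
  approximation on n − 2 degrees of freedom.
* **Kruskal–Wallis** delegates to `stats::kruskal.test()`; **Dunn** post hoc
  z-tests use pooled mid-ranks with the tie correction
  `sum(t^3 - t) / (12 (N - 1))`, Holm-adjusted by default.
* **Wilcoxon signed-rank**: zero differences dropped; exact null
  distribution (`psignrank`) when there are no ties and n ≤ 50, otherwise
  the normal approximation with continuity and tie corrections.
* **Scheirer–Ray–Hare**: joint mid-ranks, `H = SS_effect / MS_total`
  referred to chi-square. Unbalanced designs (the 17/17/13 cohort is
  unbalanced by construction) use **Type II (marginal) sums of squares**,
  which coincide with the sequential decomposition when balanced; partial
  eta-squared is `100 SS_effect / (SS_effect + SS_error)`. With a
  single-level second factor the analysis reduces exactly to
  Kruskal–Wallis. Null simulations at n = 47 put all three rank tests'
  type-I error within [0.03, 0.07] at the 0.05 level.
* A **Shapiro–Wilk gate** (`shapiro_gate()`) documents why nonparametric
  methods are used throughout.

`run_study_analysis()` applies the whole battery to a cohort table (one row
per patient and phase) and reports gaps instead of failing when a phase or
group is missing. In the factorial analysis, age enters dichotomized at the
cohort's own median so the two age groups are near-balanced by construction.

## Problem sizes and runtime

Defaults: 200 Hz sampling, 180-s protocol (60 s baseline / 60 s compression
/ 60 s recovery), 47 patients, roughly 100–300 beats per channel per
patient. A full default `run_all()` takes a few minutes on one CPU; the
per-pulse classification loop dominates. Single-patient analyses run in
about a second.

## Worked example

```{r example}
sim <- simulate_patient(patient_spec("P01"),
                        protocol_spec(baseline_s = 30, compression_s = 15,
                                      recovery_s = 10), seed = 1)
onsets <- detect_onsets(sim$icp)
segs <- segment_pulses(sim$icp, onsets)
cls <- classify_segments(segs)
table(cls$class)
w <- psi_windows(cls, 0, 30)
w[, c("window_start_s", "n_valid", "n_artifact", "psi")]
summarize_patient_psi(w)
```
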