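---
title: "zfvision: models and methods"
author: "zfvision authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{zfvision: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zfvision)
```

zfvision quantifies four larval-zebrafish visual assays — virtual prey-capture
(hunting), electroretinography (ERG), outer-plexiform-layer (OPL) fluorescence
line-scans, and the optomotor response (OMR) — and implements the proportion
and distribution statistics used to compare genotypes. Every analysis stage is
paired with a seeded synthetic-data generator that emulates the corresponding
recording modality with known ground truth, so the whole pipeline can be
validated by parameter recovery without any recorded data. This document
explains the models, the tunable parameters, the numerical choices, and what
the synthetic validation does and does not show about real recordings.

## Stimulus paradigms

Hunting assays present a small (~4.9°) bright dot swept horizontally in front
of a head-mounted larva: after a 2 s lead-in the dot crosses ~90° of the
projection screen in 3 s (~33°/s), then the system resets and the next sweep
runs in the opposite direction, always starting left-to-right. The
maximum-intensity paradigm delivers 20 such sweeps at 100% LED intensity; the
incremental paradigm delivers 10 intensity steps (0% — a no-stimulus control —
up to 90%), each step once per direction.

```{r schedule}
sched <- buildIncrementalSchedule()
sched
head(epochs(sched), 4)
```

Three paradigm-encoding choices are worth making explicit:

* **Servo-to-screen mapping.** The stimulus arm turns 20° while the dot moves
  ~90° on the screen. Only this endpoint correspondence is known, and the
  analysis never needs intermediate screen positions beyond proportionality,
  so the mapping is a single linear gain (`servoToScreenAngle()`, default
  90/20 = 4.5) rather than full projection geometry.
* **Inter-epoch gap.** The published timing leaves ambiguous whether the 4 s
  pause before the opposite sweep is measured from LED-off or from the
  position reset. The gap is therefore a constructor argument (default 4 s);
  both readings are representable.
* **OMR pseudo-random order.** The OMR assay presents seven red digital
  contrasts {170, 43, 255, 85, 0, 213, 128} in "pseudo-random" order whose
  randomization scheme is unspecified; `buildOMRSchedule()` implements it as
  a seeded uniform permutation, making any session order reproducible from
  its seed. Each contrast block runs centering (30 s), habituation (30 s,
  still grating), centering (30 s), rightward stimulus (30 s) at 14.5 mm/s
  with a 6 mm grating period.

## Hunting-event detection

The tracking software reports per-eye angles over time; left-eye convergence
is a positive deflection of the left-eye angle and right-eye convergence a
negative deflection of the right-eye angle. The detector compares each raw
track with a rolling average of itself and thresholds the residual at a
multiple of the trace's own average noise, so it adapts to recordings of
different quality:

1. For each eye, form the convergence-signed series (right eye sign-flipped),
   subtract its centered rolling mean (window `window_s`, default 0.5 s), and
   estimate the noise as the mean absolute residual (`estimateNoise()`; a
   median-based option is available for outlier robustness; for Gaussian noise
   the mean absolute residual is `sqrt(2/pi) ~ 0.8` times the SD).
2. Scan the residual for local maxima above `threshold_multiplier` (default 4)
   times the noise; maxima closer than `refractory_s` (default 0.5 s) merge,
   keeping the larger.
3. Classify: left/right peaks within `coincidence_window_s` (default 0.25 s)
   become one binocular *prey-locking* event at their mean time; unpaired
   peaks at or above `strong_multiplier` (default 6) times the noise become
   single-eye *prey-tracking* events; weaker unpaired peaks are discarded.
   Locking and tracking events are pooled downstream.

```{r detect}
truth <- EventTruth(c(10.5, 31.2), c("locking", "locking"), c(1L, 4L))
tr <- genEyeTrace(sched, truth, event_amplitude_deg = 15, noise_sd_deg = 1.5,
                  seed = 7)
detectHuntingEvents(tr)
```

Two detector readings deserve a note. First, the event scan runs on the
*residual* (raw minus rolling mean); the alternative reading — peaks of the
smoothed trace against a global baseline — responds sluggishly to brief
convergence events and would make the threshold depend on slow drift, so the
residual reading is implemented. Second, the multipliers are calibration
knobs: thresholds in the source workflow were tuned against operator-scored
events, and only noise-relative (not absolute, degree-valued) thresholds are
reproducible across rigs. Defaults of 4 and 6 noise units sit well above the
~3-noise-unit excursions of clean traces while staying far below the
deflection of a genuine convergence (~10 noise units for a 15° event over
1.5° frame noise).

The same machinery applies to total tail curvature (`detectTailEvents()`),
with one extra rule: a curvature peak only counts when its sign matches the
concurrent epoch's sweep direction, and a single flick cannot register in
both directions (cross-sign peaks within the refractory window merge,
suppressing the residual side-lobes a strong flick induces). Tail events are
excluded from default response summaries because tail tracking is unreliable
under the IR illumination of this preparation.

An epoch is scored as responded when at least one pooled event falls within
`[onset, onset + sweep + epoch_grace_s]` (grace default 1 s, covering strikes
initiated at sweep end); responses are binary per fish and epoch
(`ResponseTable`), summarized as pooled proportions (responses over delivered
stimuli), per-intensity percentages, and per-fish reaction counts.

## ERG b-wave quantification

The b-wave — the positive deflection reflecting ON-bipolar-cell
depolarization — is quantified per recording as:

* **baseline**: mean of the first 50 ms of the trace;
* **amplitude**: maximum voltage within a search window after stimulus onset
  minus the baseline (window default 1.0 s: flashes are 100 ms with 7 s
  inter-stimulus intervals, so 1 s brackets the b-wave of every intensity
  while excluding the next trial);
* **time-to-peak**: argmax time minus onset.

The synthetic trace is a difference of exponentials
`exp(-t/tau_decay) - exp(-t/tau_rise)` scaled so its analytic peak equals the
requested amplitude, preceded by a brief negative a-lobe; its closed-form
peak time `tau_r*tau_d/(tau_d - tau_r) * log(tau_d/tau_r)` gives the
time-to-peak oracle. Defaults (`tau_rise` 0.05 s, `tau_decay` 0.3 s, 10 kHz
sampling) place the peak ~108 ms after the flash, in the physiological range
for larval b-waves.

One numerical point matters for noisy traces: the maximum of *white* noise
over a ~1 s window is biased upward by roughly `sd * sqrt(2*log(N))` — about
3 noise SDs — so a raw peak search necessarily overestimates amplitude on
noisy recordings at any realistic sampling rate. `measureBWave()` therefore
accepts a rolling-mean pre-filter (`smooth_s`; 15 ms recommended for noisy
traces), which suppresses the extreme-value bias (independent samples drop
~150-fold, the residual noise SD ~12-fold) while flattening the b-wave peak
by well under 0.1%. The default leaves the trace untouched, which is exact
for clean averages.

Genotype comparisons across the five stimulus intensities (log −4 to log 0)
use per-intensity two-tailed two-sample t-tests with step-down Holm–Šídák
adjustment across the intensity family (`compareIntensitySeries()`). Welch's
unequal-variance form is the default (robust to the variance heterogeneity
typical of mutant amplitudes), with the pooled-variance form behind a flag.
One amplitude per fish per cell is assumed; whether repeated flashes were
averaged per fish upstream is an acquisition-side decision the package does
not revisit.

## OPL profile analysis

Each retina contributes one line-scan per fluorescence channel along the OPL,
starting at the ventral end of the strike zone, plus a nuclear (DAPI)
reference. Processing follows the stated order — normalize, then smooth:

1. **Normalize** (`normalizeProfile()`): divide each channel pointwise by the
   reference, then by its own maximum, giving relative intensities in [0, 1];
   arclength maps affinely onto [0, 1]. The reference is floored at
   `max(ref) * 1e-3` to avoid division blow-ups at image borders; a profile
   with more than 1% of reference samples at the floor is rejected as
   degenerate. Normalization is idempotent (the normalized reference is
   constant 1), verified to 1e-12.
2. **Smooth** (`smoothProfile()`): centered 25-point rolling average
   (matched to ~3000-point traces), partial windows at the edges.
3. **Resample** (`resampleToGrid()`): linear interpolation onto a 1000-point
   uniform grid, the minimal scheme that makes unequal-length traces
   poolable; interpolation is exact on linear segments and moves a smooth
   peak by less than one grid step.

Pooled per-channel traces carry normal-approximation 95% confidence bands
(`mean ± 1.96*sd/sqrt(n)`), and spatial co-distribution is measured by
Pearson correlation. Whether the published correlation matrix holds one
entry per (retina × channel) trace or one per channel after averaging is
ambiguous, so the package computes the per-trace matrix
(`correlationMatrix()`) and reports channel-block means
(`channelBlockMeans()`), covering both readings.

```{r opl}
profiles <- lapply(genOPLProfiles(n_retinas = 11, seed = 1),
                   preprocessProfile)
traces <- list()
for (r in seq_along(profiles))
  for (ch in c("uv_cones", "eaat5b", "eaat7"))
    traces[[sprintf("retina%02d.%s", r, ch)]] <-
      profileChannel(profiles[[r]], ch)
round(channelBlockMeans(correlationMatrix(traces),
                        c("uv_cones", "eaat5b", "eaat7")), 3)
```

The generator's default geometry encodes the anatomy the analysis is meant to
resolve: EAAT5b and UV-cone pedicles peak together in the strike zone (0.15
of arclength from the ventral origin), EAAT7 in the nasal patch (0.80), over
baselines of 0.25–0.35 with a per-retina anatomical jitter (SD 0.03) shared
by all channels of a retina.

## OMR trajectory metrics

Fish swim in rows of a 10-row arena; `assignRois()` assigns tracked points to
equal horizontal bands (boundary points go to the lower-index row — ties are
measure-zero under continuous noise, but the rule must be fixed). Per-fish
metrics inside each 30 s habituation and stimulus window:

* **Path length**: summed Euclidean distances of consecutive coordinates.
* **Speed filter** (`speedFilter()`): per-step speed thresholded at
  `multiplier` (default 2) times the trajectory's mean step speed. The
  *fast* steps are retained: larval swimming is saltatory, and OMR
  displacement is carried by swim bouts (~29 mm/s) while sub-threshold steps
  are tracking jitter. The complementary reading — discarding fast steps as
  artifacts — is available via `retain = "slow"`. The realized threshold in
  mm/s is always reported rather than hard-coded, since the published
  "~29 mm/s" anchor is ambiguous about whether it names the mean or the
  doubled threshold.
* **Rightward fraction**: distance-weighted share of retained steps with
  strictly increasing x (`dx > 0`; zero-displacement steps count as
  non-rightward). A window with no retained distance yields an *undefined*
  flag, never 0 — no data is not evidence of leftward swimming.

The trajectory generator is a bout walk: Poisson bout onsets (1 Hz), 0.15 s
bouts at 29 mm/s directed +x with the requested probability (else −x), small
tracking noise (0.02 mm) between bouts, positions clipped to the row. With
these defaults the mean step speed is ~5 mm/s, so the realized 2x threshold
(~11 mm/s) cleanly separates bouts from jitter.

## Statistics

All tests used on behavioral summaries are implemented from their closed
forms, with base-R routines serving as independent cross-checks in the test
suite:

* **Wilson score interval** for response proportions (exactly 0/1 at the
  boundary counts; 93–97% empirical coverage at n = 40, p = 0.3).
* **Two-proportion z-test** (pooled variance, two-sided normal p). A pooled
  proportion of 0 or 1 has zero variance; since 0%-intensity control epochs
  legitimately produce all-zero counts, this returns a flagged
  non-significant result (z = 0, p = 1) rather than an error.
* **Pearson chi-square** on 2×2 detection-by-display tables, df = 1, no
  continuity correction by default (matching the convention of the source
  toolchain; Yates correction behind a flag). Algebraically `z² = χ²` on the
  same table, which the tests verify to 1e-10.
* **Two-sample Kolmogorov–Smirnov**: D is the supremum ECDF difference,
  evaluated at every observed point (ties handled naturally); p from the
  asymptotic Kolmogorov series with effective n `n*m/(n+m)` by default, with
  an exact no-ties permutation option (lattice-path recursion) for
  `n*m <= 1e4`. The statistic is verified against an O(n·m) brute-force scan
  for all sample sizes up to 12.
* **Holm–Šídák** step-down adjustment for the ERG intensity family:
  `1 - (1 - p_(i))^(m-i+1)` on the ascending p-values, monotonicity
  enforced, capped at 1, unsorted.
* **Welch t-test** with Satterthwaite df (pooled-variance flag available);
  type-I error verified at 0.04–0.06 over 2000 null replicates.

In two-group reports (`statsReport()`), the per-intensity response
*distributions* of the groups are compared by KS on the vectors of
per-intensity response proportions (one value per intensity level per
group) — the reading of "intensity-specific response distributions" that the
available summaries support.

## Synthetic data as a validation surface

The generators are deterministic given (arguments, seed); one global seed
fans out to per-module streams through a stable string hash (`subSeed()`),
so stages are independently reproducible. Defaults encode the study
conditions: 20-epoch paradigms, cohort sizes of ~18–25 fish (200 for curve
recovery), a logistic intensity-response curve (floor 0.05 for spontaneous
convergence, ceiling 0.8, midpoint 55%, slope 0.15 /% — rising from ~40%
intensity to a plateau at ~70–80%), 15° convergence events over 1.5° frame
noise at 100 Hz, 11-retina OPL cohorts, and bout kinematics at 29 mm/s. The
cohort generator injects binocular locking events; since locking and
tracking are pooled in all summaries, single-eye tracking events are
exercised by the trace-level generator instead.

Validation sizes (also the problem sizes of `scripts/acceptance.R`): 20
seeded cohorts of 25 fish for detector recall/false-positive/timing, 100
seeded 200-fish cohorts for Wilson coverage of the pooled proportion, 100
seeded replicates for ERG amplitude bias at 5% noise, 100 seeded 11-retina
sets for OPL co-distribution recovery, and 100–200 fish per OMR bias level.

What passing these tests does *not* show about real data: the generators use
white Gaussian noise (real eye-tracking noise is autocorrelated and
occasionally saccade-contaminated), raised-cosine event shapes (real
convergence events are asymmetric and variable in duration), no habituation
(real response rates wane across repetitions — the package reports, but does
not model, that trend), flat baselines (no slow drift), and idealized row
confinement. The detector's noise-adaptive design is meant to absorb much of
this, but thresholds on real recordings should be sanity-checked against
operator-scored events, as in the original workflow.

## Degenerate inputs and numerical conventions

* Rolling means use shrunken (partial) windows at trace edges; odd windows
  are symmetric, even windows extend one extra sample rightward.
* A noise estimate of exactly 0 (noise-free synthetic traces with no events)
  yields zero detections rather than division by zero.
* Peak merging is greedy in time order, keeping the larger peak of any pair
  closer than the refractory period.
* `ResponseCurve` requires `0 <= floor <= ceiling <= 1`; degenerate flat
  curves (floor = ceiling) are valid and useful for null cohorts.
* Correlation requires nonzero variance; degenerate traces are rejected by
  label. The correlation matrix of pooled traces is symmetric and positive
  semidefinite up to numerical tolerance.
* File readers reject malformed numerics, non-monotone time stamps (citing
  the row) and >5% missing runs; shorter gaps are linearly interpolated and
  counted in an attribute.

## Limitations

The package consumes tracking tables, ERG voltage traces, extracted
line-scans and centroid trajectories; it does not segment video, select
confocal midsections, trace ROIs, or drive stimulus hardware. Repeated-
measures ANOVA for the OMR genotype comparison is out of scope (standard
routines apply downstream of the per-phase metrics table). Habituation
across stimulus repetitions is reported but not modeled.
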