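---
title: "Methods: wearable stress detection across laboratory and daily life"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wearable stress detection across laboratory and daily life}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stresspipe)
```

## The problem

Automatic stress detection works well in controlled laboratory settings
and much worse in daily life: consumer wristbands deliver noisier signals
than clinical sensors, subjects move freely, and the only available
ground truth in the field is the subject's own report, which is itself
noisy and subjective. `stresspipe` implements a complete analysis chain
for this problem — preprocessing, feature extraction, self-report
scoring, and a five-way evaluation that crosses training/testing
environments (laboratory vs. daily life) with label families (known
stressor context vs. self-report):

| Model | Trained on | Labels | Tested on |
|-------|-----------|--------|-----------|
| LLKC  | lab       | known context | lab (context) |
| LLSR  | lab       | self-report   | lab (self-report) |
| DDSR  | daily     | self-report   | daily (self-report) |
| LDKC  | lab       | known context | daily (self-report) |
| LDSR  | lab       | self-report   | daily (self-report) |

The scientific question is directional: when field labels are noisier
than lab labels, a model trained on clean lab self-reports (LDSR) should
transfer to daily life better than a model trained on the field's own
noisy labels (DDSR).

## Signals and preprocessing

Recordings follow the Empatica-E4 export convention: EDA (4 Hz, µS),
skin temperature (4 Hz, °C), tri-axial accelerometer (32 Hz, 1/64 g per
axis), and an interbeat-interval event list (offset and duration in
seconds). All times are UTC seconds; downstream processing uses offsets
relative to the session start, which sidesteps time-zone and DST issues.

Signals are cut into non-overlapping, half-open `[t0, t0 + 120 s)`
windows from the session start; the trailing partial window is dropped
and a beat falling exactly on a boundary belongs to the later window.
Two minutes is long enough to capture stress onset/recovery dynamics and
short enough for a responsive detector; it is also the shortest span for
which the 0.04 Hz lower LF band edge is resolvable.

**RR artifacts.** Wrist PPG produces missed and spurious beats. An
interval is flagged when it deviates from the *reference* interval by
more than 20 %. The reference is the last non-flagged interval, not the
raw predecessor: after an ectopic-like jump the next normal beat is
compared against the last clean beat, so one artifact does not cascade
(Kubios-style behaviour; the alternative reading — always the raw
predecessor — would flag the successor of every isolated jump). Flagged
intervals are replaced by a natural cubic spline fitted over
(beat index, RR) of the clean intervals; extrapolated edge replacements
are clamped to the range of the clean intervals. Windows with more than
10 % flagged intervals (strictly above: 6/60 is kept, 7/60 dropped) are
rejected, computed on the *pre-correction* flags — rejecting on
post-correction flags would let heavily corrected windows through on the
strength of interpolated data.

**EDA artifacts.** The reference tooling for EDA artifact screening is a
trained classifier; `stresspipe` ships a deterministic rule instead, so
every decision is reproducible and testable against injected ground
truth: a 5 s epoch is flagged when a steep conductance step (per-sample
change > 0.5 µS) co-occurs with a motion burst (accelerometer magnitude
SD > 0.1 g in the epoch), or when the signal leaves [0.01, 60] µS.
Sample-to-sample steps are charged to the epoch of the later sample so
boundary-crossing steps are not missed. Without an accelerometer channel
the slope rule stands alone (with a warning). Flagged epochs are
excluded sample-wise from EDA features; HRV is unaffected, so one bad
modality never costs the other.

**Tonic/phasic split.** The skin-conductance signal is split into a slow
tonic level and fast phasic SCR activity by a zero-phase order-4
Butterworth low-pass at 0.05 Hz (tonic), with phasic = signal − tonic,
making the reconstruction exact by construction. Zero-phase filtering
uses full odd-reflection padding; without padding the filter's edge
transients at this very low cutoff would corrupt a third of a 2-minute
window. A convex-optimization decomposer could be plugged in behind the
same interface; the feature set only requires a tonic/phasic split, and
the low-pass split has closed-form testable behaviour.

## Features

Per valid window, 27 features in a fixed schema order.

**HRV time domain** (corrected RR, ms; at least 10 intervals): mean RR;
SDNN (sample SD, n − 1); RMSSD; pNN50 (% of successive differences
> 50 ms); triangular index (beat count / modal bin count of the RR
histogram on the standard 1/128 s grid — "height" of the histogram read
as the modal count, the standard convention); TINN (base width in ms of
the best least-squares triangle over that histogram, apex at the modal
bin, corners searched on the bin grid, ties resolved to the narrowest
triangle); SDSD.

**HRV frequency domain**: the irregularly sampled tachogram is resampled
at 4 Hz on the window grid by natural cubic spline, mean-removed, and
its one-sided FFT periodogram (density scaling, so the rectangle-rule
integral over all bins equals the series variance — checked in the tests
to 5 %) is integrated over half-open bands VLF [0, 0.04), LF
[0.04, 0.15) and HF [0.15, 0.40) Hz, DC excluded. LF/HF is reported
missing (never infinite) when HF power is zero. Band peaks are the
frequencies of the maximal ordinate within each band. Spectra are
computed per window and averaged at session level, consistent with the
windowed design.

**EDA components** (each of phasic and tonic): mean; SD; number of peaks
(local maxima with topographic prominence ≥ 0.01 µS and ≥ 1 s
separation); number of strong peaks (prominence ≥ 0.10 µS); 20th and
80th percentiles (linear interpolation between order statistics, fixed
for reproducibility); quartile deviation (p75 − p25)/2. The prominence
thresholds follow standard SCR amplitude conventions and are
configurable; note that the 0.01 µS threshold sits at the noise floor of
a phasic trace, so the weak-peak count is a noisy feature by design and
the strong-peak count is the robust one.

Session vectors are per-feature means over valid windows, skipping
per-feature missingness, so a window that lost only its EDA still
contributes HRV. Sessions with no valid window are dropped with a
logged message, mirroring the study practice of discarding sessions with
missing reports.

## Self-report scoring

The ambulatory 5-item Perceived Stress Scale asks for happiness (H),
cheerfulness (C), anger (A), sadness (S) and frustration (F) on 1–6
scales. Positive affect counts inversely:

$$\mathrm{score} = (7 - H) + (7 - C) + A + S + F$$

The nominal range is quoted as 0–30, but 1–6 items force a minimum of 5;
the formula is implemented as printed and the exhaustive-enumeration test
asserts the true range [5, 30]. Scores below 15 are `relaxed`, 15 and
above `stressed`; the published banding lists 15 in both bands, so the
boundary assignment is explicit (to `stressed`) and configurable. For
known-context labels, baseline maps to relaxed and the stressor phase to
stressed; recovery is excluded from the two-class context task (its
arousal state is intermediate), while self-report models use all phases.

## Modeling protocol

Feature selection is correlation-based: rank by absolute point-biserial
correlation with the binary label and keep the top k (ties resolved in
schema order), with a CFS subset search
(merit \(k\,\bar r_{cf} / \sqrt{k + k(k-1)\bar r_{ff}}\), forward
best-first) available for fidelity to the original selection method.
Defaults: k = 10 for the combined modality, 5 for single modalities —
the reported best operating points.

Class imbalance (73 % of daily sessions relaxed in the emulated design)
is handled by random undersampling of the majority class to exact
balance. Features are min-max scaled to [0, 1] with parameters fit on
training data only; constant features map to 0 and test values may leave
[0, 1].

Classifiers and hyperparameters: MLP with two hidden layers of five tanh
units (logistic output, cross-entropy with a small ridge penalty,
BFGS with analytic gradients, 500 iterations, seeded initialization —
the iteration budget and learning setup are package choices, as no
reference values exist); random forest with 100 trees; kNN with k = 3;
SVM with an RBF kernel (library-default cost and gamma, recorded in the
fitted object); logistic regression thresholded at 0.5.

**Preprocessing order.** The original protocol balances, normalizes and
selects once, globally — which leaks test information into training
statistics. The default here re-fits undersampling, selection and
normalization inside every training fold; `paper_order = TRUE`
reproduces the global order exactly for comparison. Feature selection is
likewise per-fold by default. Evaluation is stratified 10-fold CV (mean
fold accuracy ± SD, confusion summed over folds) and a stratified 80/20
split; transfer models fit everything on the full lab environment and
score all daily sessions against their self-reports. One pooled model is
fit across participants (no personalization), with rows shuffled by the
run seed.

## The synthetic generator

The cohort data this design emulates are not publicly deposited, so the
package ships a generative stand-in that reproduces the *structure* the
analysis relies on; it is first-class, tested code, and its defaults are
fixed study conditions, not tuning knobs.

* **RR series**: `rr(t) = rr_mean(state) + lf_amp(state) sin(2π·0.10·t) +
  hf_amp(state) sin(2π·0.25·t) + N(0, 10 ms)`, beats accumulating
  durations. Defaults: mean RR 850/700 ms and HF amplitude 50/15 ms for
  relaxed/stressed (stress shortens RR and suppresses vagal HF
  modulation), LF amplitude 25/35 ms. A sinusoid-plus-noise model was
  chosen over a cardiac pulse-modulation model because its band powers
  are analytically known, so the spectral features can be verified
  against closed forms.
* **EDA**: tonic level 1.5/4.0 µS (relaxed/stressed) plus a slow random
  walk (0.02 µS·s^−1/2); phasic SCRs as a Poisson process at 2/8
  events·min^−1 with bi-exponential pulses (rise 0.75 s, decay 2.0 s —
  standard SCR kinetics) and amplitudes uniform on [0.1, 0.8] µS.
* **Artifacts**: RR beats scaled by factors in {0.5} ∪ [1.5, 2] at 2 per
  100 beats (all beyond the ±30 % detectability margin of the 20 % rule);
  transient EDA steps (±1.5 µS, 5–15 s) and spikes at 0.5 min^−1, each
  paired with a motion burst spanning the artifact so the epoch-level
  screen can see the conjunction. Ground-truth masks are returned for
  testing and never consumed by the pipeline.
* **Labels**: self-reports are drawn from state-consistent item
  distributions (relaxed: H, C ∈ {5, 6}, A, S, F ∈ {1..3}, scores 5–13;
  stressed: H, C ∈ {1, 2}, A, S, F ∈ {4..6}, scores 22–30), flipped to
  the opposite distribution with probability 0.05 in the lab and 0.20 in
  daily life. The item ranges are chosen so state-consistent draws
  binarize correctly at 15 with margin; the single flip parameter
  reproduces the lab-vs-field label-quality asymmetry. Field label noise
  is not quantified in the literature this emulates; 0.20 is a
  simulation condition, not a cohort estimate.
* **Study shape**: per participant one lab session
  (6 min baseline / 6 min stressor / 4 min recovery, context plus
  per-phase self-report) and six 6-minute daily sessions (self-report
  only, 73 % relaxed) — a deliberate scale-down of an hour-long lab
  protocol and 3-hour ambulatory blocks so that a 14-participant study
  simulates and processes in seconds while keeping ≥ 2 windows per
  session and ≥ 10 sessions per class for 10-fold CV. Recovery is
  generated as relaxed; its exclusion from the context task is a
  labeling decision, not a generator one.

**What the generator does not emulate:** circadian and activity-driven
physiology, respiration-linked HF coupling, participant-level trait
differences (every participant shares one parameter set), EDA
non-responders, realistic accelerometer activity patterns, and
non-symmetric self-report biases (acquiescence, recall). Passing tests
therefore demonstrate that the pipeline recovers known structure under
controlled conditions — artifact rules fire exactly where artifacts were
injected, spectral features land in the right bands, label-noise
asymmetry produces the LDSR > DDSR ordering — not that any particular
accuracy level will be reached on human data.

## Numerical choices and degenerate inputs

* Histogram bin width 1000/128 ms with edges anchored at multiples of the
  bin width; a single-occupied-bin histogram has TINN 0.
* Spline correction refuses windows with > 50 % flagged intervals (they
  are rejected anyway) and needs ≥ 2 clean intervals.
* Fewer than 2 RR intervals: detection returns all-false with a warning.
  Fewer than 10 corrected intervals: HRV features are missing for the
  window. Under 30 s of clean EDA: EDA features are missing.
* Constant RR: all band powers 0 and LF/HF missing. Constant EDA: SD,
  peak counts and quartile deviation 0, percentiles equal to the level.
* Seeds: every stochastic entry point takes a `seed` and restores the
  caller's RNG state; child seeds are derived with 32-bit-safe integer
  arithmetic, so the same run seed gives byte-identical studies and
  evaluation matrices on any platform.

## Problem sizes used in the shipped checks

The test-suite calibration runs use one 14-participant study
(126 sessions) with 50 label permutations across all 15
classifier × modality cells; the transfer-direction check uses 20
replicate studies compared by a one-sided sign test; the effect-recovery
check uses one noise-free study. These sizes give stable statistics
(binomial/SE margins are asserted, not point values) at desk scale.

## Known limitations

* The EDA artifact screen is a rule, not a learned classifier; it is
  conservative on slow drifts and cannot detect artifacts that mimic
  clean SCR kinetics without motion.
* TINN's exhaustive triangle search is quadratic in histogram bins —
  fine at 2-minute windows, slow for hour-long ones.
* The kNN "model" stores its training set (lazy learner), so its fitted
  state is its data; leakage tests account for this.
* `paper_order = TRUE` exists for replication only; its global
  preprocessing leaks test statistics into training by construction.
* Accuracies on synthetic studies should not be read as forecasts of
  human-cohort performance; only the structural and directional claims
  are transportable.
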