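---
title: "Methods: synthetic cold-pressor ECG and the pain-recognition pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic cold-pressor ECG and the pain-recognition pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its models and numerical
choices. It states no empirical result that the test suite does not itself
compute.

## 1. The synthetic world

Real cold-pressor ECG cohorts are protected personal data, so `ecgpain`
ships a generator whose output is the reference input for every downstream
stage.

**Beat model.** A heartbeat is the sum of five Gaussian components — the
classic phenomenological ECG model — with default amplitudes (mV), widths
(Gaussian σ, s) and centers relative to the R peak (s):

| wave | amp | width | center |
|------|------|-------|--------|
| P | 0.15 | 0.025 | −0.200 |
| Q | −0.10 | 0.010 | −0.035 |
| R | 1.00 | 0.012 | 0.000 |
| S | −0.25 | 0.012 | 0.035 |
| T | 0.35 | 0.050 | 0.260 |

These are typical adult limb-lead values. The Gaussian choice buys analytic
fiducials: the extremum of each wave is its center, and the ground-truth
onset/offset is placed where the component falls to 5 % of its peak (at
σ·√(2·ln 20) ≈ 2.45 σ from the center). The ground-truth R onset/offset are
the QRS boundaries — Q-wave onset to S-wave offset — because an isolated
"R-wave onset" has no physiological meaning. RR intervals are
`60/HR · exp(N(0, jitter))` with a default 3 % multiplicative jitter.

**Cohort variation.** One morphology per participant, kept across sessions:
heart rate ~ N(70, 7) bpm clipped to [45, 100]; per-wave amplitude and width
log-normal factors (σ = 0.10 and 0.05). Per session, the CPT duration is
uniform on [60, 120] s — most people endure more than a minute, not everyone
lasts two — and noise/jitter realizations differ by sub-seed. All randomness
derives from one cohort seed through a hash (`derive_seed`), so a cohort is
reproducible from `(seed, parameters)` alone.

**Pain effect.** Beats whose R peak falls in the CPT epoch get: heart rate
× 1.25, S amplitude × 0.7, T amplitude × 0.8, R amplitude × 0.9, and a
narrow −0.05 mV bump centered at the ground-truth T offset (an ST-T level
shift). These numbers are *synthetic*: no quantitative effect sizes of
cold-pressor pain on ECG morphology are available to calibrate against, so
they were chosen once as a plausible sympathetic response concentrated in
the features the importance analysis is meant to recover, and are not
revisited. `identity_effect()` gives the null world.

**Noise.** Sinusoidal baseline wander (0.10 mV at 0.25 Hz — below the
analysis band by construction), mains pickup (0.02 mV at 50 Hz) and white
noise (σ = 0.02 mV). This emulates electrode drift, powerline interference
and amplifier noise on a reasonably clean chest recording.

**What the generator does not emulate** — and hence what a green test does
not establish: beat-to-beat morphological variability (respiratory amplitude
modulation, electrode motion), ectopy and arrhythmia, nonstationary noise,
participant movement during immersion, and any real physiological coupling
between pain intensity and ECG change. Ground-truth recovery on this world
validates the *mechanics* of the pipeline, not its clinical performance.

## 2. Preprocessing

The signal is centered (mean-subtracted) and band-pass filtered with a
digital Butterworth design, 0.5–40 Hz at 1000 Hz. "Degree 4" here is the
degree of H(z): an order-2 analog low-pass prototype, transformed to a
band-pass and discretized by the bilinear transform with frequency
prewarping. The design is implemented from first principles (pole/zero
domain, then polynomial expansion) because no IIR design library is assumed
to be installed; the resulting six distinct coefficients agree with the
reference design to 4 decimal places, which the acceptance suite pins.

Zero-phase application runs the filter forward and backward, so the net
phase is zero (peaks do not move) and the effective magnitude is |H|².
Edges are handled by odd reflection padding of 3 × degree samples, the
standard choice. The test suite verifies symmetry preservation, ~unit gain
at 10 Hz (within 2 %), > 95 % attenuation of a 0.05 Hz drift, and that
filtering twice matches the |H|⁴ oracle on sinusoids.

A consequence that matters downstream: the high-pass at 0.5 Hz removes each
beat's DC content, so the inter-beat baseline of the *filtered* signal sits
below zero and wave amplitudes measured on it are shifted relative to the
clean generator amplitudes. Features are therefore ratios to the baseline
epoch (Section 4), which cancels the shift's first-order effect.

## 3. Delineation

R peaks: derivative → square → 150 ms moving-window integration → adaptive
signal/noise threshold (running estimates, threshold = noise + 0.25·(signal
− noise)) → refinement to the local maximum of the band-passed signal →
200 ms refractory enforcement. The detector is deterministic.

Delineation searches bounded windows around each R peak — P in [−250, −60]
ms, S in [0, 120] ms, T in [120, 450] ms (clipped at neighbouring beats) —
and places onsets/offsets where the signal crosses a fraction (default 10 %,
5 % to match the ground-truth convention) of the wave's prominence.
Two numerical choices here were forced by experiment:

* **Local baseline.** Prominence and crossing levels are measured from the
  median of the PR segment (R − 130…70 ms), not from zero, because of the
  filtered-baseline shift described above. With zero-referenced thresholds,
  S-offset crossings essentially never occur.
* **Turning-point fallback.** At CPT heart rates the P wave rides on the
  previous T wave and the crossing level may not be reached inside the
  search span; the fiducial then falls back to the extremum of the walked
  span (the turning point), a standard delineation surrogate. Without it,
  ~30 % of CPT beats of fast-heart-rate participants are dropped, which
  biases the beat-count features and distorts the injected heart-rate
  effect.

Beats whose full ten-fiducial set cannot be located, or violates the
within-beat ordering contract, are dropped and counted. Inverted R polarity
raises an error rather than being silently corrected.

## 4. Features and normalization

Windows are 20 s with 75 % overlap (5 s step), fully inside one epoch;
an epoch of L seconds yields ⌊(L−20)/5⌋+1 windows (57 for 300 s, 21 for
120 s). A fiducial belongs to a window when its index is in [start, end)
(half-open, 0-based throughout). Distances use only same-type consecutive
peaks that are both in-window. `*_onoffdist` is read as the per-beat
onset-to-offset duration (wave width); the alternative reading —
gaps between consecutive onsets and offsets of different beats — would
essentially duplicate the `*_distance` features, so the width reading is
both more informative and isolated in one function should anyone disagree.
Windows with any undefined feature are flagged and dropped, never imputed.

Each feature is divided by its mean over the baseline windows of the same
participant-session (computed on window-level features, not raw signal).
Baseline rows therefore normalize to mean exactly 1, and all amplitude
features become scale-equivariant: multiplying a recording by any constant
leaves them unchanged. A zero or non-finite baseline mean is an error naming
the feature.

The labeled dataset keeps baseline (class 0) and CPT (class 1) rows only.

## 5. Designs, models, metrics

Three train/test designs: *dependent* — 5 repetitions of stratified 2-fold
CV (10 evaluations; rows, not participants, are stratified, so one
participant's windows can appear on both sides — deliberately, as the
easiest setting); *session-independent* — train on all session-1 rows, test
on all session-2 rows; *participant-independent* — per held-out participant,
train on session-1 rows of the others, test on the holdout's session-2 rows.
Disjointness of every train/test pair is asserted at construction. Metrics
are averaged over evaluations with equal weight.

The eight families use the reference defaults: AdaBoost (50 depth-1 stumps,
learning rate 1, real-boosting update), CART (gini, unlimited depth), kNN
(k = 5, Euclidean; k is capped at the training size), LDA, L2 logistic
regression (C = 1, realized as ridge with λ = 1/(nC)), random forest (100
trees, √p features per node, bootstrap of size n), and C-SVM (C = 1,
tolerance 10⁻³; RBF γ = 1/(p·Var(X))). The trees, forest, boosting and the
SMO SVM solver are implemented in the package (C++), since no suitable
implementations are in the dependency footprint; the CART splitter visits
candidate features in random order with strict-improvement selection, so
exact ties between equally separating features are broken uniformly at
random rather than by column order. All stochastic fits consume seeds
derived from the experiment seed.

Metrics come from the confusion matrix with CPT positive; ratios with zero
denominators return 0 and are flagged. The implementation is checked against
a brute-force counting oracle on a thousand random label vectors.

## 6. Importance

Coefficient families (LDA, logistic) report absolute coefficients; tree
families report accumulated gini decrease; SVM and kNN report permutation
importance — the mean drop in balanced accuracy over 10 seeded shuffles of
one feature column, scored on held-out rows. Models are fitted on the first
evaluation of the design's plan and permutation is scored on that
evaluation's test rows (for session-independent, the unique split); the
repeat count, the scoring metric and the fit/score rows are all choices the
method leaves open, made once and fixed here. Raw scores are min–max scaled
to [0, 1] per model; an all-equal score vector maps to all-zero with a
degeneracy flag instead of erroring. Consensus is the mean scaled score
across models, ties broken alphabetically.

**A caution discovered by the test suite.** With the default effect sizes,
window averaging (~25 beats per window) shrinks per-window noise roughly
five-fold, and *fourteen* of the 21 features become perfect class
separators. Importance methods degenerate under total separability: a
single tree (and each boosting stump) needs exactly one split, so its
importance is one-hot on a randomly tie-broken feature; permuting any one of
several redundant perfect features changes nothing, so permutation scores
collapse to ~0 and their min–max rescaling amplifies noise; and coefficients
on near-collinear separators are arbitrary. The cross-model consensus
ranking *within* the set of perfect separators is therefore tie-break noise,
and the injected S-amplitude effect is not reliably ranked above the other
injected effects — only above the genuinely uninformative features. The
acceptance suite states the stronger expectation (S amplitude in the
consensus top-3) and is allowed to stay red on it; treating a
consensus-importance rank among perfectly redundant features as meaningful
would be the real error.

## 7. Reproducibility and budgets

Every stage draws from streams derived from one seed; cohorts are lazy
(recordings realized one at a time, so a 72-recording cohort never holds all
signals in memory); all artifacts are plain text (CSV/JSON). The full-scale
test — a 36 × 2 cohort through preprocessing, delineation, features and all
three designs over all eight models — runs in a few minutes on one CPU, and
the suite asserts the end-to-end budget explicitly.
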