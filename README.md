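# ecgpain

Pain recognition from a single-lead ECG during a cold-pressor protocol.

## The problem

The cold pressor task (CPT) — immersing the forearm in ~7 °C water for up to
two minutes — evokes acute pain and a sympathetic cardiovascular response.
This package implements, as a tested and reusable R pipeline, an ECG-only
analysis of such protocols: can windows of heartbeats recorded *during* the
CPT be told apart from windows recorded at rest, using only morphological
features of the ECG cycle, and which features carry that decision?

The protocol has five contiguous epochs per participant-session:

| epoch    | duration | condition                      |
|----------|----------|--------------------------------|
| baseline | 300 s    | seated rest (negative class)   |
| warm1    | 120 s    | forearm in 37 °C water         |
| cpt      | ≤ 120 s  | forearm in 7 °C water (positive class) |
| warm2    | 120 s    | forearm in 37 °C water         |
| rest     | 300 s    | seated rest                    |

Real recordings of this kind are typically protected personal data, so the
package ships a first-class synthetic cohort generator: each heartbeat is a
sum of five Gaussian wave components (P, Q, R, S, T) with analytic ground
truth for all fiducials, participants vary in rate and morphology, and the
CPT epoch applies a documented synthetic "pain" effect (tachycardia plus S/T/R
amplitude modulation and an ST-T level shift). Everything downstream is
developed and validated against that ground truth.

## The method

1. **Preprocessing** — the signal is centered and filtered with a zero-phase
   (forward–backward) digital Butterworth band-pass, 0.5–40 Hz at 1000 Hz,
   with transfer function of degree 4:

   `H(z) = (0.0131 − 0.0261 z⁻² + 0.0131 z⁻⁴) / (1 − 3.6504 z⁻¹ + 5.0050 z⁻² − 3.0586 z⁻³ + 0.7040 z⁻⁴)`

   The design (analog prototype → band transform → bilinear transform with
   prewarping) is implemented from first principles and reproduces these
   coefficients to 4 decimal places.
2. **Delineation** — a Pan–Tompkins style R detector (derivative → square →
   moving-window integration → adaptive threshold, 200 ms refractory), then
   bounded physiological searches for P/S/T extrema and
   prominence-fraction onsets/offsets.
3. **Features** — 20 s windows with 75 % overlap (5 s step); per window the
   21 features `{P,R,S,T}_peaks`, `{P,R,S,T}_amplitude`, `{P,R,S,T}_distance`,
   `{P,R,T}_onsetamp`, `{P,R,T}_offsetamp`, `{P,R,T}_onoffdist`; every
   feature divided by its baseline-epoch mean per participant-session.
4. **Evaluation** — binary baseline-vs-CPT classification under three
   designs: *dependent* (5 × stratified 2-fold CV), *session-independent*
   (train session 1, test session 2) and *participant-independent*
   (leave-one-participant-out), over eight classifiers (AdaBoost, decision
   tree, kNN, LDA, logistic regression, random forest, linear and RBF SVM),
   scored with accuracy, balanced accuracy, F1, MCC, precision and recall.
5. **Importance** — per-family importance (coefficients / gini decrease /
   permutation), min–max scaled to [0, 1] per model for cross-model
   comparison.

## Worked example

```r
library(ecgpain)

co  <- generate_cohort(n_participants = 4, n_sessions = 2, seed = 7)
tab <- cohort_dataset(co)           # preprocess -> delineate -> features
res <- run_experiment(tab, "session_independent", seed = 7)
summary_matrix(res)
```

```
              accuracy balanced_accuracy f1 mcc precision recall
adaboost             1                 1  1   1         1      1
decision_tree        1                 1  1   1         1      1
knn                  1                 1  1   1         1      1
lda                  1                 1  1   1         1      1
logistic             1                 1  1   1         1      1
random_forest        1                 1  1   1         1      1
svm_linear           1                 1  1   1         1      1
svm_rbf              1                 1  1   1         1      1
```

Every model separates CPT from baseline perfectly here because the default
synthetic effect sizes are large relative to the window-averaged noise — see
the methods vignette for why that is, and for what a perfect score does and
does not establish. Shrinking the effect toward identity degrades balanced
accuracy toward 0.5 (chance), which the test suite checks explicitly.

A filter design and a single recording:

```r
fl <- design_bandpass(0.5, 40, 1000, 4)
round(fl$b, 4)   # 0.0131  0.0000 -0.0261  0.0000  0.0131
round(fl$a, 4)   # 1.0000 -3.6504  5.0050 -3.0586  0.7040

rr  <- realize_recording(co, 1)
ft  <- process_recording(rr$recording)   # 21 features per 20 s window
```

## Command line

```sh
Rscript -e 'ecgpain::ecgpain_cli()' simulate out=cohort participants=4 sessions=2 seed=1
Rscript -e 'ecgpain::ecgpain_cli()' run out=results participants=4 seed=1
Rscript -e 'ecgpain::ecgpain_cli()' report dir=results
```

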