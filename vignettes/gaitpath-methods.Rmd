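---
title: "Classifying foot conditions from gait-cycle kinematics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying foot conditions from gait-cycle kinematics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Instrumented gait analysis of the foot produces, per subject, a dozen
functional joint angles (Heidelberg Foot Measurement Method conventions:
tibiotalar flexion, medial arch angle, subtalar inversion, and so on), each
summarized as a stride-averaged *mean* series and a between-stride
*standard-deviation* series on a cycle-normalized grid of 101 points
(0–100% of the gait cycle), together with the foot-off instant that
separates stance from swing. Reading these curves by eye is slow and
subjective. `gaitpath` automates the path from curves to a clinical label —
one of six foot conditions or typically developed feet — and, just as
importantly, reports *which* kinematic features drove each decision.

## Pipeline

The stages, in order:

1. **Derived series.** For each angle's mean series $U$, the discrete
   first gradient
   $V[k] = \tfrac{1}{2}(U[k+1] - U[k-1])$
   captures the rate of change across the cycle, and the difference from
   normative
   $DN[k] = |U[k] - U_{norm}[k]|$
   captures deviation from the per-angle reference $U_{norm}$, the
   point-wise average over typically developed subjects. The central
   difference is undefined at the endpoints $k = 0, 100$; rather than
   inventing one-sided values, the gradient series lives on the interior
   grid $k \in [1, 99]$ and every window that touches it is intersected
   with that domain.

2. **Phase-wise scalar features.** The cycle is split at
   $r = \mathrm{round}(\text{foot-off})$ into stance $[0, r]$ and swing
   $[r, 100]$. The boundary index belongs to both phases: the foot-off
   instant ends stance and starts swing, and sharing it guarantees both
   windows are nonempty for any admissible foot-off. Per angle and phase we
   take the extrema and their timings (in % cycle, earliest occurrence on
   ties) of the mean, gradient and deviation series, the max and its timing
   of the std series, and the window-averaged deviation; the full-cycle
   range of motion of the mean series is added once per angle. That is 15
   features per angle per phase, 31 per angle, and with the two global
   foot-off scalars $12 \times 31 + 2 = 374$ features per subject. Timings
   are reported in % gait cycle, which on this grid coincides with the
   sample index.

3. **Preprocessing.** Missing series cells are filled by per-cell medians
   (middle-pair average on even counts). Features are min–max scaled to
   $[0,1]$ with training-derived minima and maxima; constant training
   features map to 0 and are flagged; test values are deliberately not
   clipped. A natural-log transform (after shifting columns positive) is
   available but off by default — skewing the inputs toward normality
   brought no measurable benefit.

4. **Feature selection.** Two selectors run independently on the scaled
   training features and their outputs are intersected. Recursive feature
   elimination uses a linear one-vs-rest SVM, dropping the feature with the
   smallest sum of squared decision-function coefficients one at a time
   (step 1); subset sizes along the elimination ranking are scored by
   stratified-CV macro balanced accuracy and the maximum wins, smaller
   subsets on ties. Balanced accuracy is used rather than plain accuracy
   because the class sizes are strongly imbalanced (20 to 100 subjects per
   class). The second selector keeps features whose random-forest impurity
   importance reaches the mean importance — the threshold is otherwise
   unspecified in the published procedure, and the mean adapts to the
   feature count. An empty intersection falls back to the union with a
   warning.

5. **Classification.** Four probabilistic members — SVM (Platt-calibrated
   probabilities), random forest, one-vs-rest ridge-penalized logistic
   regression, and exact brute-force KNN — are combined by a weighted soft
   vote $P = \sum_m w_m P_m$, $w \ge 0$, $\sum w = 1$; the label is the
   argmax with ties to the lexicographically first class. Weights are
   chosen by sampling the 4-simplex and keeping the vector with the best
   validation balanced accuracy. Iterative learners stop on a loss change
   below $10^{-4}$; the logistic regression is capped at its tuned
   iteration maximum. Hyperparameters come from a randomized search (grid
   search for the logistic regression, whose convergence is the fragile
   part), or from the published tuned preset via `paper_preset()`.

6. **Evaluation.** One-vs-rest confusion counts per class give balanced
   accuracy, recall, precision and F1; zero-denominator ratios are reported
   as 0 and flagged. Macro averages are unweighted means over classes — the
   alternative prevalence-weighted reading would let the 100-subject
   control class dominate exactly the imbalance the per-class view is meant
   to expose. Repeated cross-validation supports both 3× repeated
   stratified 5-fold (default) and leave-one-out; leave-one-out retrains
   every member $n$ times per repeat, so it is guarded by a sample cap and
   the k-fold scheme is advised above it.

7. **Explanation.** For each explained subject, perturbed instances are
   drawn per feature from the quartile bins of the training background,
   weighted by an exponential kernel on standardized distance
   (width $0.75\sqrt{d}$), and a weighted ridge surrogate sparsified to the
   top-weight features is fitted to the model's probability for the
   subject's *true* class (explaining the predicted class is a
   configuration option). Explanations are computed in original units —
   degrees and % cycle — by composing the scaler into the prediction
   function, so a weight reads directly as "probability change per degree".
   Per condition, up to 20 subjects are sampled without replacement from
   the full cohort and features are ranked by mean absolute weight; the
   report carries, per model, how many sampled subjects had the feature in
   their own top 5 (the bar-length analog), with ties broken by canonical
   feature order.

## Leakage policy

The published retrospective procedure computes the normative reference,
imputation medians, scaling and feature selection on the whole dataset and
uses true labels for class-conditional imputation. `gaitpath` ships both
readings:

* `paper_mode` mirrors that ordering faithfully, including
  class-conditional imputation of the test partition.
* `leakage_safe` (default) fits the normative reference, imputer, scaler
  and selection on the training partition only, and — after experimenting
  with the alternative — imputes *both* partitions with pooled training
  medians. Filling training gaps class-conditionally while test gaps get
  pooled medians turned out to bias selection toward features that only
  survive the label-aware fill (window minima of the
  difference-from-normative series are the canonical casualty: one pooled
  cell in a patient's stance window collapses the minimum to a
  control-like value). Applying the identical transform at fit and predict
  time removes that failure mode; it is also the only transform a deployed
  classifier could apply to an unlabeled subject.

In `leakage_safe` mode the test labels live in a sealed vault object that
records every access; the pipeline opens it exactly once, in the evaluation
stage, and the test suite asserts the access log.

## The synthetic cohort

The clinical dataset behind this design is not publicly deposited, so the
package carries a generator that emulates its structure: the same seven
classes with the same subject counts (58, 64, 20, 40, 41, 25 patients and
100 controls; 348 in all), 101-point series, foot-off near 60 ± 2% of the
cycle, per-class demographics drawn from the published means and carried as
metadata only. Each angle has a fixed three-harmonic base waveform (package
constants, not fit to any real data); subjects jitter it with an additive
offset (sd 1.5°), a ±10% amplitude factor and a ±2%-cycle phase shift, and
carry a nonnegative $|N(1.5°, 0.5°)|$ stride-variability envelope.

Pathological classes additionally receive planted effects from a registry
whose *directions* follow clinical expectation — planovalgus lowers and
cavovarus raises the medial arch angle, clubfoot shifts forefoot/ankle
abduction and supination, hallux rigidus damps hallux and tibiotalar
motion, a consolidated calcaneal fracture offsets subtalar inversion and
inflates its stride variability, tibiotalar osteoarthritis with partial
replacement damps tibiotalar motion — but whose *magnitudes* (4–10° offsets,
0.45–0.7 amplitude factors, a 2.5× variability inflation) are calibrated
once for signal recoverability against the generator's jitter, not for
biofidelity. No published waveform statistics exist to calibrate against.

What passing tests on this cohort do and do not show: they demonstrate that
the pipeline recovers effects of the planted kind at these magnitudes —
separable classes, near-ceiling test scores — not that real HFMM waveforms
are classifiable at the published level. Real stride-averaged kinematics
have correlated angles, heteroscedastic variability, and pathology effects
that are neither piecewise-constant nor phase-aligned; none of that is
modeled. The generator's missing values are injected uniformly at random,
a deliberate simplification of marker dropout, which clusters.

## Numerical choices and degenerate inputs

* Foot-off rounds half-up to the boundary index; values whose boundary
  would leave an empty phase (below 0.5 or at/above 99.5% of cycle) are
  rejected.
* Extremum-timing ties take the earliest grid index, which is
  deterministic and independent of storage order.
* The RFE score trace defaults to every subset size when there are at most
  60 features and a ~40-point near-geometric grid above that; the
  elimination itself always proceeds one feature at a time.
* Median convention: mean of the two middle order statistics.
* Constant features: scaled to 0 (flagged), excluded from LIME
  perturbation with a note, inverted back to their constant.
* The LIME surrogate solves a ridge system with penalty $10^{-3}$ on the
  standardized scale before the sparse refit; the refit adds $10^{-8}$ to
  the normal-matrix diagonal purely for numerical safety.
* All stochastic stages consume explicit stage seeds derived from one
  master seed; identical configuration and seeds give byte-identical
  metrics JSON.

## Problem sizes used in the shipped checks

The test suite and the acceptance script exercise the full default cohort
(348 subjects, 374 features, 1000 LIME perturbations per subject, 20
subjects per condition, 5-fold selection CV) once end-to-end, and run the
repeated selection-recovery property on scaled-down cohorts of 12 subjects
per pathological class plus 20 controls over 10 seeds — the full
374-feature competition is retained while keeping the step-1 RFE at these
sizes. Unit tests use cohorts of 8 subjects per class.

## Command-line interface

`inst/cli/gaitpath.R` is a thin `Rscript` wrapper: `simulate`, `derive`,
`extract` and `select` expose the corresponding stages with CSV/JSON
artifacts, and `run-all` executes the whole pipeline and writes every
artifact (cohort, normative reference, feature table, selection report,
metrics JSON, relevance report) to a directory. Training, evaluation and
explanation are reached through `run-all`: they share fitted state that has
no plain-text serialization, and the package functions remain the interface
for granular control.

## Known limitations

* The published scores and selected-feature identities were computed on
  the non-deposited clinical dataset and are not reproducible here; the
  synthetic cohort validates mechanism, not clinical performance.
* The random-forest fitter exposes minimum node size, depth, feature
  candidates and bootstrapping, but not a separate minimum-split
  parameter; the published value (2) is recorded in the preset and implied
  by minimum leaf 1.
* The logistic regression is fitted by penalized coordinate descent; the
  published stochastic-average-gradient solver choice is recorded but not
  re-implemented, as the fitted optimum, not the optimizer, is what the
  pipeline consumes.
* KNN search is exact brute force; the published tree-based neighbor
  search and its leaf size are recorded in the preset but irrelevant to
  exact results at these sample sizes.
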