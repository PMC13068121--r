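---
title: "Lateralizing unilateral vestibular deficits from laboratory test asymmetries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lateralizing unilateral vestibular deficits from laboratory test asymmetries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A unilateral vestibular schwannoma silently weakens the vestibular organs of
one ear. The affected side is known from MRI, which makes such cohorts an
ideal benchmark for a different question: *how well does each laboratory
vestibular test, on its own or in combination, point at the correct side?*
The standard battery quantifies:

* **vHIT** -- the vestibulo-ocular reflex (VOR) gain of all six
  semicircular canals during rapid head impulses (gain = eye velocity /
  head velocity; lateral canals abnormal below 0.8, vertical canals below
  0.7);
* **caloric irrigation** -- low-frequency lateral-canal function from the
  maximal slow-phase velocity of nystagmus under warm (44°C) and cold
  (30°C) irrigation of each ear;
* **VEMPs** -- cervical (saccular) and ocular (utricular) vestibular-evoked
  myogenic potentials, via peak-to-peak amplitudes;
* **SVV** -- the subjective visual vertical, the mean signed error (degrees)
  when resetting a tilted line to vertical in darkness (normal within
  ±2.2°).

`vestasym` implements the complete analysis as a reusable pipeline:
asymmetry statistics, a normative correction for the monocular-vHIT
recording bias, fold-aware preprocessing, descriptive side-correspondence
summaries, and cross-validated side prediction — together with a synthetic
cohort generator that provides ground truth for every stage.

## Asymmetry statistics

All ratio metrics are Jongkees-style normalized differences scaled to
percent. With `LL, RL, LA, RA, LP, RP` the six canal gains:

* `RLLL = (LL - RL) / (RL + LL) * 100` (lateral canals);
* `RALP = (LP - RA) / (RA + LP) * 100` and
  `LARP = (LA - RP) / (LA + RP) * 100` (the two diagonal vertical-canal
  planes, each mixing an anterior canal with the contralateral posterior
  canal);
* the composite anterior–posterior measure
  `cmpAP = (RP·LP - RA·LA) / (RP·LP + RA·LA) * 100`, built from the gain
  *products* that distinguish the plane-average composite from the
  diagonal-product composite;
* the VEMP asymmetry ratio `AR = (R - L) / (R + L) * 100` on peak-to-peak
  amplitudes;
* the caloric canal paresis
  `CP = ((RC + RW) - (LC + LW)) / (RC + RW + LC + LW) * 100`;
* the SVV shift, the mean of the six signed trials.

Two sign conventions coexist in the printed formulas: the vHIT metrics are
left-minus-right while AR and CP are right-minus-left. The package keeps
the as-printed values for reporting and adds an explicit
`canonicalize_signs()` layer (positive = right side affected) before any
side scoring or classification; the per-metric orientation map
`{rlll:+, ralp:+, larp:+, cmp_ap:+, vemp:-, caloric:-, svv:+}` is a
package constant, so the orientation of every downstream number is
auditable.

A property worth knowing (and covered by the tests): under a full
left/right swap of the raw measurements, RLLL, AR, CP and SVV negate,
the RALP and LARP planes *exchange* (`RALP ↦ -LARP`), and cmpAP is
**invariant** — it contrasts posterior against anterior gain products and
algebraically carries no left/right information. This is consistent with
its near-chance discriminative performance.

## Monocular vHIT gain-bias correction

Monocular goggles record one eye only and systematically inflate the
measured side's gains. The correction estimates the "normative"
left-minus-right gain difference per canal pair in a comparison group with
control-like vHIT function and subtracts it from each patient's **left**
gain (`apply_offset()`); right gains are untouched. Subtracting from the
left member reproduces `corrected difference = raw difference - offset`
exactly, which is the property the correction exists for. The alternative
(splitting the offset half/half across sides) would additionally preserve
exact mirror symmetry of corrected ratio metrics, but changes no
conclusion; the left-sided convention is kept and documented. Corrected
gains are floored at 0.01 so that ratio denominators stay positive, and
one-sample t-tests (`left_right_ttests()`) document the bias before and
after correction. Offsets are estimated once from the full comparison
group: that group is never classified, so fold-awareness does not apply to
it.

## Fold-aware preprocessing

The per-patient metric table is cleaned in a fixed order — 1-nearest-
neighbour imputation, winsorization, then range normalization (descriptive
path) or standardization (classifier path) — with every statistic fitted
on training rows only and refitted inside each cross-validation fold:

* **Imputation**: each missing metric is copied from the nearest training
  row, with Euclidean distance over mutually observed columns rescaled by
  `sqrt(p/m)` (`p` columns total, `m` shared); ties break toward the
  smallest training-row index, and donors that do not observe the needed
  column are skipped in distance order. `k = 1` is fixed a priori: with a
  small clinical sample, averaging over larger neighbourhoods would shrink
  asymmetry magnitudes toward the mean.
* **Winsorization**: values beyond the training mean ± 2 SD (sample SD)
  are replaced by the most extreme *observed* training value still inside
  the bound in that direction — not by the bound itself, so imputed
  replacements are always values the metric actually takes.
* **Normalization / standardization**: division by the training range
  (max − min) for descriptive comparability across metrics with different
  units; zero-mean unit-variance scaling for classifiers. Zero-range or
  zero-variance columns are dropped with a warning.

Transformed matrices carry a stage ledger so that re-applying a stage of
the same fitted model is a no-op; `fit_preprocess()` returns the
transformed training matrix directly (a training row must never be imputed
"against itself").

## Cross-validated side prediction

Classification uses leave-one-out folds: for each patient, preprocessing
and classifier are refitted on the other n − 1 patients. Three classifier
families with a priori fixed hyperparameters are provided: unregularized
logistic regression (IRLS, 200 iterations, tolerance 1e-8, held-out
log-likelihood-ratio scores capped at ±30 to tame exact separation),
Gaussian naive Bayes (per-class per-feature normal densities, variance
floor 1e-9), and a linear soft-margin SVM (cost 1). The positive class is
+1 (right side affected) everywhere.

**Why two AUC routes.** Pooling raw leave-one-out decision values into one
ROC is pessimistically biased in small samples: each fold's model shifts
slightly *away* from the held-out patient's class, and for weak features
the per-fold coefficient sign becomes label-dependent, which can push the
pooled AUC of a truly uninformative metric far below 0.5. The package
therefore (a) calibrates each held-out score to its midrank percentile
within the fold's training-score distribution before pooling
(`score_cal`), which restores cross-fold comparability for the ROC curve,
its bootstrap CI and the Youden operating point; and (b) reports as the
headline cross-validated AUC the **leave-pair-out** estimate
(`lpo_auc()`): for every (positive, negative) pair the model is refitted
with both patients held out and the pair is compared within that one
model. Because every pair-fold excludes exactly one patient of each class,
the fold-composition asymmetry cancels and the estimate is close to
unbiased. A residual small-sample effect remains even then: the refitted
coefficient tilts against the held-out pair's difference (an influence-
function effect of order 2/n), so on *zero-signal* features whose
full-data slope happens to be very near zero, cross-validated AUCs can
still fall well below 0.5. This is a property of cross-validating a
learned direction at n ≈ 68, not of any particular implementation, and it
cannot be removed without letting the held-out patient influence the fold
model (which the leakage tests forbid).

On top of the per-metric analyses the package provides the SVM-weight
feature ranking (one linear SVM on the full standardized cohort, metrics
ordered by |weight|), the stepwise multivariate trace (cumulative logistic
models in ranking order, plateau = smallest model within 0.005 of the
maximum AUC), grouped canal-proxy `{RLLL, RALP, LARP}` versus
otolith-proxy `{cVEMP, oVEMP}` models, percentile-bootstrap AUC intervals
(2000 stratified resamples by default, seeded), and the paired bootstrap
AUC comparison (`2·min(P(Δ ≤ 0), P(Δ ≥ 0))` with resamples at exactly
zero contributing ½ to each tail; single-class resamples are redrawn and
counted).

## The synthetic cohort generator

No patient-level data are deposited, so the generator emulates the
*statistical structure* of such a cohort with known ground truth. Defaults
are the study conditions: 68 patients, 33 comparison-group subjects,
balanced sides.

* **Canal gains**: truncated normals — affected lateral 0.60 (SD 0.10)
  vs unaffected 0.95 (SD 0.05); verticals 0.55/0.90 with the same SDs;
  additive measurement noise SD 0.02; gains floored at 0.05.
* **Recording bias**: left-minus-right offsets (lateral −0.06, anterior
  −0.01, posterior −0.03) added to the right gains of *every* subject,
  patients and controls alike — largest for laterals, smallest for
  anteriors, mirroring the qualitative pattern of the comparison-group
  t-tests.
* **VEMPs**: one amplitude base per subject (cVEMP ~ N(150, 40) µV floored
  at 5; oVEMP ~ N(10, 3) µV floored at 0.5), per-side multiplicative noise
  (SD 0.15); the affected side's cVEMP is multiplied by 0.4 and its oVEMP
  pathway by 0.6.
* **Caloric**: one responsiveness base per subject ~ Gamma(shape 8, scale
  2.5 °/s); the affected ear is multiplied by 0.35; per-condition
  multiplicative noise (SD 0.15). A single subject-level base keeps
  healthy inter-ear asymmetry well inside the 25 % pathological bound,
  as it is clinically.
* **SVV**: the subject's tilt is `side · (3° + N(0, 8°))` with
  per-trial SD 1.5°. The 8° between-subject term models central
  compensation and idiosyncratic verticality bias; it is what keeps the
  SVV weakly discriminative at the group level (as observed clinically)
  despite a consistent mean tilt toward the lesion.
* **Discordant patients**: with probability `p_flip` (default 0.05) the
  whole deficit block is generated as if the tumor were on the opposite
  side while the true label is unchanged — pre-existing contralateral
  deficits, atypical hyperresponses, or human error.
* **Missingness**: per-test-block (all four caloric conditions vanish
  together, all six SVV trials, both amplitudes of a VEMP), at observed
  rates oVEMP 4.4 %, SVV 5.8 %, caloric 7.3 %, cVEMP and vHIT 0 %.
* **Outliers**: each patient measurement is tripled (SVV: shifted +15°)
  with probability 0.02, to exercise winsorization. Controls stay clean —
  a comparison group is screened for normal function.

Every subject draws from an RNG substream derived from `(seed, index)`, so
enlarging a cohort never changes earlier subjects and runs are
bit-reproducible. What the generator does *not* emulate: tumor size and
location effects (no quantitative description is available), raw eye/head
velocity traces, age structure, and any correlation between a patient's
deficit severity across tests beyond the shared affected side. Passing
tests on this generator therefore demonstrate the pipeline's correctness
and calibration, not clinical performance on real patients.

## Numerical choices and degenerate inputs

* Pathological thresholds are strict (`gain < 0.8`, `|CP| > 25`,
  `|SVV| > 2.2`): boundary values are normal.
* A side score of exactly 0 is "undefined" and counted as a
  non-correspondence.
* Zero-variance t-tests report p = 1 (zero mean) or the degenerate limit
  p = 0 with a warning (nonzero mean).
* Bilaterally absent VEMP or caloric responses are domain errors (the side
  is undefined), not silent zeros.
* ROC ties: thresholds sweep unique score values; the trapezoidal area
  then equals the midrank concordance probability exactly, which the test
  suite verifies against an exhaustive pairwise oracle.
* Operating-point ties break toward higher sensitivity, then lower
  threshold.

## Problem sizes used by the test suite

The suite validates on cohorts of 16–68 subjects, 500-subject control
groups for offset-recovery checks, 200 bootstrap-uniformity replicates at
500 resamples each, and leave-pair-out estimation at the full study size
(n = 68, ~1150 model refits per metric). These sizes were chosen so each
statistical check has the power it needs while the whole suite stays
comfortably interactive.

## Known limitations

* The cross-validated-AUC small-sample tilt described above: on
  zero-signal metrics, cross-validated AUCs are mildly pessimistic and
  occasionally far below 0.5; interpret near-chance AUCs with their
  bootstrap intervals, not as evidence of "anti-prediction".
* With whole-block discordance (`p_flip`), no combination of tests can
  recover the flipped patients, so combined models plateau near
  `1 - p_flip` rather than at 1.
* The gain-bias correction inherits the comparison group's sampling noise
  (n = 33 by default); offsets carry standard errors for this reason.
* cmpAP is mirror-invariant and therefore cannot lateralize by
  construction; it is retained for completeness and comparison.
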