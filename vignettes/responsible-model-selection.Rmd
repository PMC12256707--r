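---
title: "Responsible selection of clinical risk classifiers: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Responsible selection of clinical risk classifiers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fairselect)
```

## The problem

Binary classifiers for clinical outcomes — here, 5-year myocardial infarction
(MI) and stroke among people with type 2 diabetes — are usually compared on a
single discrimination metric. That practice hides two things a deploying
clinician needs to know: whether the model performs equally well across
demographic subgroups, and *why* it predicts what it predicts. `fairselect`
treats assessment, selection and explanation as one workflow, with fairness
and explainability given the same first-class status as AUC.

## Stage 1: assessment

**Threshold choice.** Sensitivity, specificity and accuracy depend on the
classification threshold. The package scans every observed unique score as a
candidate threshold under the rule "positive if score ≥ t" and keeps the one
maximizing `u·sensitivity + (1−u)·specificity`. The default `u = 2/3` encodes
the clinical judgement that missing a true MI or stroke is costlier than a
false alarm; ties are broken toward the lower threshold, i.e. toward higher
sensitivity, for the same reason. `u` is a tunable in `[0,1]`: `u = 1` yields
the minimum score (sensitivity 1), `u = 0` the most specific candidate.

**Fairness.** For a protected attribute with subgroups `s`, the Relative
Parity of Performance Score is

$$\mathrm{RPPS} = 1 - \max_s \frac{|\mathrm{AUC}_s - \mathrm{AUC}|}{\mathrm{AUC}}.$$

Three deliberate semantics:

* RPPS is **relative** — deviations are scaled by the overall AUC, so models
  with different baseline discrimination are comparable.
* It is **not clamped**: a subgroup deviating by more than the overall AUC
  drives RPPS negative, and that information is kept.
* It penalizes deviation in **either direction**: a subgroup served *better*
  than average still lowers parity, because it means another group is served
  relatively worse.

Subgroups whose test rows contain a single outcome class have no defined AUC;
they are reported as unevaluable and excluded from the max with a warning
rather than silently dropped or allowed to crash the report. AUC is the
default base metric because it is threshold-agnostic, but `rpps()` accepts
any metric through the same two arguments.

AUC itself is computed by the Wilcoxon rank statistic (ties counted ½), which
equals the trapezoidal area under the empirical ROC curve; the test suite
verifies it against brute-force pair enumeration and against an independent
ROC implementation.

## Stage 2: selection

Each model is reduced to the pair (accuracy at its optimized threshold,
RPPS for a chosen attribute) and scored by `w·accuracy + (1−w)·RPPS` as the
preference weight `w` sweeps `[0,1]`. Because each model's score is affine in
`w`, the best-model map is piecewise constant and its boundaries are exact
line intersections; `tradeoff_curve()` reports them as exact rationals of the
four inputs rather than snapping to the grid, and ties are listed rather than
broken — selection is advisory output for a human decision-maker. Accuracy
(not AUC) enters the trade-off because it is the threshold-dependent quantity
a deployed classifier actually delivers; pairing it with the threshold-free
RPPS spans both views of performance.

## Stage 3: explanation

Three methods are composed because they answer different questions:

* **Permutation importance** (global, performance-oriented): what does the
  model's AUC lose when a feature's information is destroyed? Each of
  `n_bootstrap = 100` replicates resamples the training rows with
  replacement, *refits* the model, computes a baseline AUC on the out-of-bag
  rows, and scores each feature by baseline minus permuted AUC. Refitting
  captures fitting variability, not just scoring noise; out-of-bag evaluation
  avoids the optimism of scoring training rows (which rows to use is a
  genuinely open choice; this is the conservative one). CIs are percentile
  bootstrap intervals; negative importances are reported, not floored — they
  are a useful overfitting signal.
* **Shapley values** (local, attribution-oriented): how is one prediction
  split among features? Values are computed on the **margin (log-odds)
  scale** with the training sample as an interventional background, because
  additivity is exact there for linear models: for a model with margin
  `b0 + Σ βᵢxᵢ`, the value is exactly `βᵢ(xᵢ − mean background)` and the
  efficiency identity (base + Σφ = margin) holds to machine precision. For
  non-linear families a permutation-sampling estimator is used; expectations
  over absent features are taken over *all* background rows, orderings are
  enumerated exhaustively when `p! ≤ shapley_samples` (making the estimator
  exact), and per-cell standard errors are reported otherwise. **Relative**
  Shapley values divide each row by its total attribution Σφ so contributions
  sum to 1 per row; the normalizing convention (by Σφ, rather than by the
  prediction or by Σ|φ|) is a documented package choice, and rows with
  near-zero total attribution are flagged and excluded from summaries because
  the ratio is unstable there.
* **Partial dependence** (global, shape-oriented): the average model output
  as one feature is swept over its observed range (50 equally spaced points;
  the observed values for binary indicators), everything else held at
  observed values. Curves are emitted on **both** scales — mean risk and mean
  log-odds — since clinicians read risks while log-odds make linear structure
  visible; the log-odds curve averages per-row margins (not the logit of the
  mean risk), which makes the PDP of a logistic model exactly affine with
  slope equal to its coefficient, a property the tests exploit. A histogram
  of the feature's observed values accompanies each curve so flat or steep
  regions can be judged against data support.

`explain_model()` composes the three, carrying the `top_k = 3` features by
mean permutation importance into the PDP panel.

## The synthetic cohort generator

`accord_like_spec()` emulates the structure of a large T2D
cardiovascular-outcomes trial: 10 biomarkers as independent normals with the
published means/SDs (age 62.8 (6.66) y, BMI 32.2 (5.4), SBP 136.5 (17.1),
HbA1c 8.3 (1.1), ...), five categoricals with the published marginals (38%
women; 74/19/7% White/Black/Hispanic; 36% CVD history; 35% insulin; 12%
smokers), logistic outcome models with fixed coefficients, intercepts
calibrated by bisection to prevalences of 9.1% (MI) and 2% (stroke), and 6%
of rows carrying one missing predictor cell (MCAR — the source only reports a
row-level incomplete rate).

Design choices, made once:

* **Independent features, no copula.** The workflow's correctness does not
  depend on realistic correlation structure, while known logistic truth is
  exactly what parameter-recovery tests require.
* **Effect sizes** were set to give the generating models a population AUC of
  about 0.74 for both outcomes, matching the moderate discrimination typical
  of published CVD risk classifiers; directions follow the clinical
  narrative (CVD history and age drive MI; HbA1c and blood pressure drive
  stroke; modest negative associations for women and Black participants).
* **Outcomes are independent given features**; MI and stroke are treated as
  separate classification tasks.
* **Calibration** uses monotone bisection of the intercept over a fixed
  100,000-draw covariate sample to tolerance 1e-3 on the mean event
  probability.

What passing tests on this generator do **not** show: robustness to
correlated or non-Gaussian biomarkers, informative missingness, survival-time
structure, or treatment effects. The generator validates the *machinery*
(metrics, trade-off arithmetic, attribution identities, recovery of known
coefficients), not clinical transportability.

## Preprocessing conventions

* **Complete-case filtering**, no imputation, scoped to role columns only.
* **Reference (k−1) dummy coding** named `"feature=level"`; single
  coefficients like `gender=women` are then directly interpretable, and
  tree-based families are insensitive to the choice. Unseen levels at encode
  time are an error, not a silent column of zeros.
* **70/30 split with round-half-up** training size (so 9635 rows give
  6745/2890), unstratified by default with a stratified option.
* **Balanced inverse-frequency class weights** `n/(2·n_c)`, applied where
  each backend supports weighting.

## Numerical choices and degenerate inputs

* Risk scores are clamped to `[1e-12, 1−1e-12]` before the logit so margins
  stay finite for models that emit exactly 0 or 1.
* Threshold candidates are the observed unique scores; the argmax tie-break
  is toward sensitivity with a 1e-12 tolerance.
* Trade-off ties use a 1e-12 tolerance and report all tied models.
* Cross-validation folds are unstratified with a fixed seed; folds whose
  held-out part is single-class are skipped from the mean CV AUC.
* All randomness is drawn under locally scoped seeds, so identical
  spec + seed reproduce byte-identical cohorts, splits, fits and
  explanations, and callers' RNG streams are untouched.

## Problem sizes used in validation

The test suite exercises parameter recovery at n = 50,000 (coefficients and
calibrated prevalences), oracle equivalences on instances up to n = 50
(where brute-force enumeration is feasible), dense-grid trade-off checks at
10,001 weights, and bootstrap importance with 20–40 replicates on cohorts of
a few hundred rows — sizes chosen so each property is tested at the scale
where its failure mode would show, while the full suite stays fast enough to
run on every change.

## Known limitations

* OCT/OFS-style globally optimal trees and cardinality-constrained logistic
  models are represented by depth-limited greedy trees and penalized
  regression; the adapter contract accepts any classifier, so a user with
  access to such solvers can wrap them.
* RPPS is reported without confidence intervals; subgroup AUCs on small test
  subgroups are noisy, and interval estimation is a natural extension.
* The sampling Shapley estimator costs `O(orderings × background × features)`
  model evaluations per explained row; it is intended for moderate feature
  counts.
* Explanations describe model behavior, not causal effects of risk factors.
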