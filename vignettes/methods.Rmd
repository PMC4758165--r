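---
title: "Validating biomarker-classifier combinations across independent cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating biomarker-classifier combinations across independent cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xmittn)
```

## The problem

Established CSF Alzheimer's biomarkers (A&beta;42, t-Tau, p-Tau181) are
diagnostic but not staging markers: their levels stay relatively stable
after disease onset and do not separate mild cognitive impairment due to AD
(MCI-AD, defined here by a CSF t-Tau/A&beta;42 ratio of at least 0.39) from
mild AD dementia. Candidate non-amyloid non-tau analytes -- here complement
C3 and factor H (FH) -- might carry that staging information, but their
levels are confounded by age, diagnosis, and assay platform, so univariate
group comparisons are uninformative and machine-learning models fit to a
single cohort overfit.

`xmittn` implements a four-stage procedure that treats the *combination* of
a biomarker panel and a learning algorithm as the hypothesis, and tests it
with an explicit null distribution in a training cohort followed by a
frozen-model transfer to an independently recruited test cohort.

## The four stages

Let the training cohort contain the two stage groups (MCI-AD labeled 0,
mild AD labeled 1).

1. **Repeated random splits.** `make_splits()` draws `n_folds` (default
   1000) independent partitions into a train set (default n = 180) and a
   disjoint internal CV set (default n = 50), sampling without replacement
   within each fold. Splits are class-stratified by default so that every
   fold preserves the cohort's stage proportion to within integer rounding;
   without stratification a CV set can end up single-class, in which case
   that fold is recorded as missing and removed from the denominator.

2. **Dual-experiment fitting.** Each of nine classifiers is fit on every
   train set under two feature sets -- Experiment 1: age, sex, APOE
   &epsilon;4 carriage, A&beta;42, t-Tau, p-Tau181; Experiment 2: the same
   plus harmonized C3 (`c3_z`) and FH -- and scored on the matching CV set.
   Ranking performance is summarized by the Gini index
   $G = 2\,\mathrm{AUROC} - 1$ (Somers' D), computed by midranks with ties
   counted one half, so $G = 0$ is exactly chance and $G = 1$ a perfect
   ranking. The same splits serve every algorithm &times; experiment cell;
   cells differ only in learner and feature set.

3. **Null-hypothesis testing.** Under the null (classification no better
   than chance) the fold Gini values scatter around 0, so the empirical
   fraction of folds with $G \le 0$ estimates the probability of
   chance-or-worse performance and is used as the cell's p-value
   (`stage3_pvalue()`). Values at or below zero are counted, because
   below-chance ranking is also "no better than chance". Cells with
   p &lt; 0.05 (strict, unadjusted -- each survivor still faces an
   independent cohort) are selected.

4. **Frozen-model bootstrap validation.** Each selected combination is
   refit once on the *full* training cohort and frozen
   (`freeze_final_model()`); the frozen model -- including its
   training-derived standardization -- is applied unchanged to the test
   cohort. `bootstrap_validate()` draws (default) 1000 class-balanced
   bootstrap test sets of 50 MCI-AD + 50 AD, sampled with replacement
   within class (replacement is forced: a test cohort may hold fewer
   subjects than slots). The fraction of replicate Gini values at or below
   0 is the external p-value; sensitivity, specificity and accuracy are
   averaged over replicates, and per-subject sampling/labeled-AD tallies
   accumulate.

### P(AD) staging

`compute_pad()` turns the tallies into a per-subject dementia-probability
score: the fraction of samplings in which the model labeled the subject
mild AD. Subjects split at 50 % into `LIKELY_MCI` (P(AD) &lt; 0.5) and
`LIKELY_DEMENTIA` (P(AD) &ge; 0.5; the boundary is on the dementia side).
`compare_groups()` then contrasts longitudinal cognition between strata:
each subject's executive or memory Z-scores are summarized either as the
per-subject mean (`LEVEL`, in Z) or the per-subject least-squares slope
(`SLOPE`, in Z per month; at least two visits at distinct months required),
and the two strata are compared with Welch's unequal-variance t
construction, reporting the difference (low-P(AD) minus high-P(AD)
stratum), a 95 % CI and a p-value. This per-subject-summary + two-sample
design is the simplest procedure that yields the reported style of
quantities (a Z difference with CI for a level contrast, a Z-per-month
difference with CI for a slope contrast); a mixed-effects variant is
deliberately out of scope.

Note a consequence of the single-frozen-model convention: a deterministic
model scores a given subject identically in every replicate, so P(AD) from
one validation is exactly 0 or 1. Intermediate values arise when tallies
are pooled over several validations (e.g. both experiments, or an ensemble
of fold models); the tally/score contract supports that directly.

## The nine classifiers

All learners run behind one contract (`fit_classifier()`, `score_model()`,
`predict_model()`): continuous scores are class probabilities where the
learner has them, otherwise signed distances to the decision boundary
(perceptron, SVM), which is all a rank-based Gini needs; hard labels
threshold the score at 0.5 (probabilities) or 0 (margins), with ties going
to label 1. No hyperparameters are tuned anywhere; the reference
configuration is a declared convention, overridable through
`algorithm_spec()`:

| name | implementation | defaults |
|---|---|---|
| LOGISTIC | binomial GLM (`stats::glm.fit`) | standardized features |
| PERCEPTRON | averaged perceptron (compiled in-package) | 100 epochs, lr 1, standardized |
| DECISION_TREE | CART (`rpart`) | cp 0.01, minsplit 20 |
| BOOSTED_TREE | boosted stumps (`xgboost`, depth 1) | 100 rounds, eta 0.3 |
| GRADIENT_BOOSTING | boosted trees (`xgboost`, depth 3) | 100 rounds, eta 0.1 |
| NAIVE_BAYES | Gaussian naive Bayes (`e1071`) | -- |
| RANDOM_FOREST | probability forest (`ranger`) | 500 trees |
| KNN | `class::knn` | k = 5, standardized |
| SVM | RBF-kernel SVM (`e1071`) | cost 1, standardized |

Design notes. The SVM uses a non-linear (radial-basis) kernel -- the extra
freedom in modeling interactions is the point of including it. Its decision
values are sign-calibrated against the training labels so that larger
always means more AD-like. "Boosted decision tree" is realized as boosted
depth-1 trees (stumps) under logistic loss, the classical boosted-stump
ensemble, distinguishing it from the depth-3 gradient-boosting
configuration. The averaged perceptron is implemented in compiled code
inside the package (no pre-installed R package provides one) and is checked
against a pure-R reference implementation in the test suite.
Scale-sensitive learners standardize features internally with
*training-fold* statistics only, stored in the frozen model -- CV-fold or
test-cohort statistics never leak into a fit. Per-fold fit seeds derive
deterministically from (master seed, fold, algorithm name), so the entire
stage is reproducible from one integer.

## Cohort harmonization

Raw C3 is right-skewed and strongly assay-dependent (the two study cohorts
were measured on different platforms, and one ran systematically lower).
`normalize_c3()` therefore z-scores natural-log C3 against the *cohort's
own* cognitively normal reference subjects:
$z = (\ln c_3 - m_{\mathrm{ref}})/s_{\mathrm{ref}}$, with sample mean and
sample SD (n &minus; 1). The choice of log base is immaterial (it cancels
in the ratio); natural log is used and documented for reproducibility.
Normalization is strictly per cohort: a cohort-level multiplicative assay
factor only translates $\ln c_3$ and is removed exactly by the
subtraction -- this is the property that justifies comparing models across
platforms, and the synthetic generator reproduces it so the test suite can
verify it. FH is approximately normal and enters untransformed.

Missing data are handled by complete-case exclusion at feature-matrix
construction with a logged manifest (no imputation). When both experiments
run together, the analysis restricts to subjects complete for *all*
requested feature sets so that every cell shares identical splits.

## The synthetic generator

`generate_cohort()` draws per-group (NORMAL / MCI_AD / AD) feature
distributions whose defaults are the published group-level summaries of
the two study cohorts (`cohort_spec_adni()`, `cohort_spec_emory()`;
`table1_reference()` holds the values). Structure beyond the marginals:

* analytes are truncated normal at 0 (redraw); log C3 is normal on the
  reference scale (`ref_logc3_mean` 10.0 &asymp; 22 ng/mL, `ref_logc3_sd`
  0.35 -- placeholder values of realistic magnitude, as the published text
  prints no absolute C3 summaries, only z-scores);
* within-group age regressions: log C3 rises with age in every group
  (default 0.012/yr); FH rises with age only in the AD-consistent groups
  (default 8 pg/mL/yr), reflecting the reported diagnosis &times; age
  interaction. Both coefficients are placeholders of plausible magnitude
  (the fitted values are in unpublished supplementary material) and are
  centered at the group age mean so group means/SDs stay interpretable;
* a cohort-level multiplicative C3 assay factor (default 0.6 for the
  test-like cohort) emulates the between-platform shift;
* every MCI_AD subject is rejection-sampled until t-Tau/A&beta;42 &ge;
  0.39, so the inclusion rule holds by construction (bounded by a
  rejection budget);
* longitudinal visits at 0/6/12/18/24 months (the study protocol followed
  subjects at 6- or 12-month intervals over a longer span; the reduced
  2-year span keeps simulated designs small) with per-subject random
  intercepts (SD 0.4 Z), random slopes (SD 0.01 Z/month) and residual SD
  0.2 Z; patient groups decline, dementia faster.

Features are otherwise independent within group -- the published summaries
give no covariance structure. That is a real limitation: passing tests
show the pipeline behaves correctly under the *assumed* structure (null
calibration, signal recovery, harmonization), not that real cohorts meet
those assumptions, and correlated confounding (e.g. age entangled with
stage) could degrade real-data performance in ways these simulations do
not probe.

Two derived configurations drive the calibration suites.
`generate_null_pair()` copies the MCI-AD distributions onto the AD group
in both cohorts and applies the inclusion-rule constraint to both stages,
so the stage labels carry no information at all; `generate_staged_pair()`
starts from that configuration and shifts only the AD group's log-C3 and
FH means (default &minus;1 SD each) and its executive slope (default
&minus;0.035 Z/month). Consequently the six-feature experiment stays null
while the eight-feature experiment carries the signal -- the qualitative
pattern the method is supposed to detect.

## Numerical and procedural choices

* Gini via midranks is exactly the pair-counting statistic (ties one half)
  and invariant under strictly increasing score transforms; the suite
  checks both against brute-force enumeration.
* p-values count Gini &le; 0 rather than strictly = 0; with continuous
  scores, mass exactly at 0 is negligible and below-chance performance is
  "no better than chance".
* A p-value exactly at &alpha; is *not* selected (strict inequality).
* Constant (zero-variance) feature columns in a training fold are centered
  but not scaled.
* Degenerate inputs error loudly: single-class training labels,
  single-class Gini, empty feature matrices, references with fewer than
  two subjects or zero log-C3 variance, tallies exceeding sampling counts,
  strata with fewer than two usable longitudinal subjects.
* All randomness flows from one master seed through a string-hash seed
  derivation (`derive_seed()`), keeping every derived seed below 2^31 and
  making training, validation and generation independently reproducible.

## Reference problem sizes

The heavy checks run at deliberately reduced but statistically meaningful
sizes, stated here as the package's reference conditions: null calibration
uses 20 independently generated cohort pairs (230-subject training, 73
patient test) at 100 folds with all nine algorithms and both experiments;
signal recovery uses 20 replicates at 200 folds for the SVM; slope-gap
recovery uses 100 replicates of two strata of 5 subjects with five visits
each. The full default (1000 folds, 1000 bootstrap replicates) runs in a
few minutes for a single cohort on one core.

## Calibration caveat, stated honestly

Because the CV folds are resampled from one finite cohort, the fold Gini
values of a *realized* null cohort are correlated: a cohort whose 230
subjects happen to carry an accidental feature-label association yields
consistently positive CV Gini, and occasionally (a few percent of
algorithm &times; experiment cells) a Stage-3 p below 0.05. This is
intrinsic to repeated-subsampling CV on a single cohort, not a defect of
the implementation -- it is exactly why the procedure insists on the
independent-cohort Stage 4, which filters most (though, as any test at
&alpha; = 0.05 must, not all) of these through. The bootstrap p-value of
Stage 4 measures resampling noise around the model's realized test-cohort
Gini, so its false-positive rate under the null is roughly the probability
that an independent test draw shows an accidental Gini above ~0.17 --
about one in ten of the rare Stage-3 survivors. The package reports both
stages' p-values so users can see the full chain rather than a single
binary verdict.

## Limitations

* No hyperparameter search, no probability calibration, no nested CV --
  faithfully mirroring the validated procedure, which performs none.
* No mixed-effects longitudinal modeling; the slope comparison is a
  two-sample contrast of per-subject summaries.
* No MCI&rarr;dementia conversion-time analysis.
* The generator's independence assumption within groups, and its
  placeholder age-regression and C3-scale constants, bound what synthetic
  results can say about real cohorts.
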