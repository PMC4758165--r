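# xmittn

Cross-validated null-hypothesis testing and frozen-model bootstrap
validation of biomarker–classifier panels, with per-subject
dementia-probability staging.

## The problem

CSF amyloid and tau biomarkers diagnose Alzheimer's disease but do not
stage it: their levels are stable after onset and fail to separate mild
cognitive impairment due to AD (MCI-AD, CSF t-Tau/Aβ42 ≥ 0.39) from mild
AD dementia. Candidate staging analytes — complement C3 and factor H — are
confounded by age, diagnosis and assay platform, so neither univariate
comparison nor a classifier tuned on one cohort settles whether they carry
staging information. `xmittn` is for biomarker researchers who want to test
a *biomarker-panel × learning-algorithm combination* as the hypothesis, in
two independent cohorts, with explicit null distributions at every step.

## The method

Stage classification is scored by the Gini index, *G* = 2·AUROC − 1
(Somers' D): 0 at chance, 1 for a perfect ranking.

1. **Repeated random splits** of the training cohort (default 1000 folds of
   180 train + 50 internal-CV subjects, class-stratified, disjoint).
2. **Dual-experiment fitting**: nine classifiers (logistic regression,
   perceptron, decision tree, boosted stumps, gradient boosting, naive
   Bayes, random forest, k-NN, RBF-SVM) are fit on every train set under
   Experiment 1 (age, sex, APOE ε4, Aβ42, t-Tau, p-Tau181) and Experiment 2
   (the same + harmonized C3 and FH), and scored on the matching CV set.
3. **Null-hypothesis testing**: for each algorithm × experiment cell the
   p-value is the empirical fraction of CV folds with *G* ≤ 0
   (chance-or-worse); cells with p < 0.05 (strict, unadjusted) are
   selected.
4. **Frozen-model bootstrap validation**: each selected model is refit once
   on the full training cohort, frozen, and applied unchanged to an
   independent test cohort through 1000 class-balanced bootstrap replicates
   (50 + 50, drawn with replacement within class). The external p-value is
   again the fraction of replicate Gini values ≤ 0; sensitivity,
   specificity and accuracy are averaged over replicates.

Per-subject tallies from Stage 4 yield a dementia-probability score
**P(AD)** — the fraction of samplings in which the model called the subject
mild AD — splitting subjects at 50 % into likely-MCI and likely-dementia
strata whose longitudinal executive/memory trajectories can be compared
(per-subject mean level or least-squares slope, Welch two-sample contrast).

C3 is harmonized per cohort by z-scoring log C3 against the cohort's own
cognitively normal reference subjects, which removes platform-level
multiplicative assay shifts exactly.

Because the real study cohorts are access-restricted, the package includes
a seeded synthetic-cohort generator whose defaults reproduce the published
group-level summaries (`table1_reference()`), including the age dependence
of C3/FH, the between-platform C3 shift, the MCI-AD inclusion rule, and
longitudinal decline — enough structure to exercise and test every stage
end to end. See the methods vignette (`vignettes/methods.Rmd`) for the
model, assumptions, and what synthetic results do and do not show.

## Worked example

Simulate a training/test pair in which *only* C3 and FH separate the
stages (−1 SD each in the AD group), then run all four stages:

```r
library(xmittn)

pair  <- generate_staged_pair(c3_shift = -1, fh_shift = -1, master_seed = 42)
train <- normalize_c3(pair$train)   # 135 MCI-AD + 95 AD + 115 normals
test  <- normalize_c3(pair$test)    #  51 MCI-AD + 22 AD +  25 normals

fit <- run_training_stage(train, n_folds = 200, master_seed = 42)
print(fit)
#> <xmittn_training> adni_like_train: 230 subjects, 200 folds
#>  p-values (fraction of folds with Gini <= 0):
#>                    EXP1 EXP2
#> LOGISTIC          0.870 0.00
#> PERCEPTRON        0.820 0.00
#> DECISION_TREE     0.520 0.00
#> BOOSTED_TREE      0.720 0.00
#> GRADIENT_BOOSTING 0.510 0.00
#> NAIVE_BAYES       0.905 0.00
#> RANDOM_FOREST     0.645 0.00
#> KNN               0.325 0.01
#> SVM               0.440 0.00

model <- freeze_final_model(train, "SVM", "EXP2",
                            selection = select_models(fit), master_seed = 42)
val <- bootstrap_validate(model, test, n_boot = 1000, master_seed = 42)
print(val)
#> <bootstrap_validation> SVM x EXP2: 1000 replicates of 50+50
#>  p = 0.000; mean sensitivity 54.5 %, specificity 82.3 %, accuracy 68.4 %

pad <- compute_pad(val)
table(pad$stratum)
#> LIKELY_DEMENTIA      LIKELY_MCI
#>              21              52
compare_groups(test, pad, domain = "EXECUTIVE", comparison = "SLOPE")
#> <slope_comparison> EXECUTIVE SLOPE: difference 0.007 Z/month
#>  (95 % CI -0.004 to 0.018), p = 0.2074
#>  groups: LIKELY_MCI n = 52, LIKELY_DEMENTIA n = 21
```

Reading the output: with no signal in the six standard features, every
Experiment-1 cell is far from significant (p-values 0.33–0.91), while
adding C3/FH makes every Experiment-2 cell significant — the qualitative
pattern the method exists to detect. The frozen SVM transfers to the
independent test cohort (external p = 0.000) with moderate per-subject
accuracy (68 %), and P(AD) reclassifies 21 of 73 test patients as likely
dementia. At this seed the executive-slope contrast between strata is
positive (likely-MCI stratum declines 0.007 Z/month more slowly) but not
significant — with an imperfect classifier the stratum contrast dilutes the
generator's −0.035 Z/month gap, a useful reminder that staging and slope
recovery are distinct questions.

A command-line wrapper with `simulate`, `train`, `validate` and `stage`
subcommands is installed at `inst/cli/xmittn.R`.

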