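---
title: "Modelling clinical disability from smartphone keystroke dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling clinical disability from smartphone keystroke dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(keydyn)
```

## The problem

People with multiple sclerosis (pwMS) are assessed at clinic visits every few
months with instruments such as the Expanded Disability Status Scale (EDSS,
0–10 in half-point steps), the Nine-Hole Peg Test (NHPT, seconds; higher is
worse manual dexterity) and the Symbol Digit Modalities Test (SDMT, 0–105;
higher is better information-processing speed). Typing on a smartphone
exercises the same fine-motor and cognitive systems many times a day, so the
*timing* of key presses and releases — keystroke dynamics — is a candidate
passive digital biomarker that samples disability continuously between
visits, without burdening the patient.

`keydyn` implements that idea as a tested pipeline: it turns raw press/release
event streams into daily keystroke features, collapses them into composite
fine-motor and cognition scores, and trains subject-level binary classifiers
for clinical diagnosis (healthy control vs pwMS) and for binarized severity
levels of EDSS, NHPT and SDMT. Because the cohorts that motivated this design
are not publicly available, the package ships a seedable synthetic cohort
generator with the statistical structure the analysis assumes; every stage is
exercised against it.

## Keystroke sequences

With $t_n^p$ and $t_n^r$ the press and release timestamps (ms) of the $n$-th
key among $N$ keys in an interval:

$$\mathrm{HT}_n = t_n^r - t_n^p, \qquad n = 1,\dots,N$$
$$\mathrm{FT}_n = t_{n+1}^p - t_n^r,\quad
  \mathrm{PPL}_n = t_{n+1}^p - t_n^p,\quad
  \mathrm{RRL}_n = t_{n+1}^r - t_n^r, \qquad n = 1,\dots,N-1$$

Hold time (HT) and flight time (FT) are the primitives; press–press and
release–release latency satisfy the exact identities
$\mathrm{PPL}_n = \mathrm{HT}_n + \mathrm{FT}_n$ and
$\mathrm{RRL}_n = \mathrm{FT}_n + \mathrm{HT}_{n+1}$ on unfiltered data,
which the test suite asserts on thousands of random streams. Three
conditional sequences capture error-correction and paralinguistic behaviour:
the After Punctuation Pause (APP; FT following a punctuation key) and the
Pre-/Post-Correction Slowing (PreCS/PostCS; FT immediately before/after a
backspace).

Three choices here are genuinely open and are fixed as follows:

* **Sessions.** A release-to-press gap above 60 s starts a new session, and
  FT/PPL/RRL never span sessions. This removes the "keyboard on screen but
  idle" artefact; the bound is configurable (`session_gap_ms`).
* **Outlier filter.** The retained ranges default to HT ∈ (0, 2000] ms and
  FT ∈ [0, 5000] ms (PPL/RRL ∈ [0, 7000]); negative flight times (key
  rollover) are dropped, and the conditional sequences inherit the FT bounds
  so a removed flight time never survives as an APP/PreCS/PostCS value. The
  published analyses name such a filter without quantifying it; the bounds
  are config-exposed (`kd_filter_config()`).
* **Suggestion taps** (word-suggestion buttons) are not typing-rhythm keys:
  they enter the count features only, never the timing sequences.

Daily aggregation applies a configurable statistic registry — by default
mean, median, SD, interquartile range, maximum and 95th percentile — to each
sequence per subject-day, alongside the total event, backspace and
suggestion counts. A statistic of an empty sequence is missing, never zero;
a subject-day with no events produces no row.

## Composite scores

To reduce the feature space ahead of small-cohort model fitting, daily
features are collapsed into composite scores: each composite is the
unweighted mean of its z-scored members available that day, with the
standardisation parameters estimated on the training split only. The default
clusters follow the hypothesis that timing statistics reflect fine-motor
function and error/paralinguistic statistics reflect cognition:

| composite | members |
|---|---|
| `fmcs_central` | mean, median of HT, FT, PPL, RRL |
| `fmcs_dispersion` | SD, IQR of HT, FT, PPL, RRL |
| `ccs_central` | mean, median of APP, PreCS, PostCS |
| `ccs_dispersion` | SD, IQR of APP, PreCS, PostCS |

Membership is additionally pruned data-driven: a member is kept only if its
mean absolute pairwise correlation with the rest of its cluster reaches
`min_abs_correlation` (default 0.5 — "highly correlated" is otherwise
unquantified; the best-connected member is always retained so a cluster
cannot empty itself). Count features pass through unclustered.

## The three-stage classifier

For a clinical target, each labelled subject-visit contributes a window of
composite-score day-rows: days within $\pm w_d$ days of the visit (for
diagnosis, where controls have no visits, the first $w_d$ observed days from
baseline — a trailing window, switchable to centred), keeping only days with
at least $\tau_d$ keystroke events. Both $w_d$ and $\tau_d$ are
hyper-parameters; `kd_grid_search_wd_tau()` optimises them against the
cross-validated AUC-ROC and returns the full heatmap.

1. **Stage 1 — normalise + impute.** Features are z-scored with training
   parameters, then missing entries (days where a sequence was empty) are
   filled by a chained-equation imputer: round-robin linear regressions of
   each feature on the others, iterated from mean-imputation until the
   largest update falls below `tol` (1e-3) or `max_iter` (10) rounds. The
   final-round coefficients are stored, so transforming new data never
   refits. Constant features are an error (nothing to standardise), and an
   all-missing feature is reported by name.
2. **Stage 2 — soft-voting ensemble.** Independent classifiers, averaged on
   the probability scale. Menus per target follow the published best
   ensembles: diagnosis RF+LR; EDSS RF+LR+QDA; NHPT LR+GNB+SVM; SDMT
   LR+KNN+SVM. All members train with balanced class weights (or balanced
   priors where the estimator has no weight interface — QDA, GNB, whose
   posteriors are re-balanced analytically). The SVM's decision values are
   calibrated to probabilities with a Platt-style sigmoid fitted on the
   training fold, since soft voting needs probabilities and the margin
   classifier does not supply them natively.
3. **Stage 3 — subject prediction.** The subject-visit probability is the
   arithmetic mean of the per-day ensemble probabilities,
   $\hat y = \tfrac1d \sum_i \tilde y_i$, thresholded at 0.5 (configurable).
   A window with zero qualifying days yields a flagged abstention, never a
   silent 0.5.

Binarization conventions: SDMT ≤ 55 is the positive (impaired) class;
NHPT > cutoff and EDSS > cutoff are positive, with the cutoff a median split
re-estimated on each training fold (leakage-safe) or frozen at a fixed value
(e.g. the published full-sample medians NHPT 20.40 s, EDSS 3.5) — both
behaviours are supported because the published cutoffs equal full-sample
medians.

Evaluation is grouped everywhere: an 80/20 subject-disjoint stratified
hold-out split, leave-one-subject-out cross-validation (LOGOCV) in the
training set with *all* preprocessing (cutoff, composite z-parameters,
imputer, optional feature selection) refitted inside each fold, AUC-ROC with
a grouped percentile bootstrap CI (default 1,000 resamples, single-class
resamples redrawn), and sensitivity/specificity/accuracy/prevalence at the
0.5 threshold.

### Feature selection

`kd_prefilter_features()` drops columns by missingness (> 0.3) and variance
(< 1e-8). `kd_rfe_consensus()` then runs recursive feature elimination under
five estimators (LR, RF, QDA, GNB, SVM) with grouped 5-fold CV: each
estimator eliminates the least important feature stepwise (|coefficient| for
LR, impurity importance for RF, a permutation AUC-drop otherwise), recording
its AUC-versus-size trace; the consensus set takes the size maximising the
mean trace and the features most recurrent across the estimators' best
subsets, ties broken toward features eliminated latest. By default
`kd_logocv()` does *not* re-run RFE inside folds: the bundled composite
space has ~7 columns, where backward elimination is a cost with no
statistical benefit; `select_features = TRUE` restores the fully nested
behaviour, and the selection machinery is validated directly on planted-
feature benchmarks.

### Interpretation

`kd_exact_shapley()` attributes a per-day prediction to its features with
exact Shapley values under the interventional value function — $v(S)$ is the
mean model output over a background sample with the coalition's features set
to the instance's values — enumerated over all $2^f$ coalitions (capped at
$f \le 15$; the selected feature sets here are far smaller). Enumeration is
exactly reproducible and lets the test suite assert the efficiency, symmetry
and null-player axioms to 1e-9 and agreement with the permutation definition
for $f \le 6$. Day-level explanations are pooled into global importances by
averaging absolute values per feature.

## The synthetic cohort generator

`kd_simulate_cohort()` emulates the observational design the pipeline
expects: 24 healthy controls and 102 pwMS by default; pwMS followed for 365
days with five clinical visits at days {0, 91, 182, 273, 364}; controls
contributing about 88 days of typing from baseline and no clinical
assessments. A latent severity trait $s \in [0,1]$ (low Beta stratum for
controls, Beta(2,2) for pwMS) drives everything:

* **Latencies** are log-normal — the simplest positive, right-skewed family
  matching inter-key latency shape — with the subject's log-mean shifted by
  `effect_hold · sdlog_hold · s` (and analogously for flight times; both
  effects default to 0.25 SD per unit severity), plus an idiosyncratic
  subject offset (SD 0.03) and a day offset (SD 0.04).
* **Typing volume**: sessions arrive Poisson (mean 4/day) with geometric
  lengths (minimum 5 keys, mean ~20), about 80 keys on an active day; a day
  is empty with probability 0.15 — the source of real missingness that
  exercises the $\tau_d$ mask and the imputer.
* **Outcomes**: NHPT increases (17 s + 8 s·s), SDMT decreases (68 − 25·s) and
  EDSS increases (1 + 6·s, rounded to the half-point scale, clipped to
  [0, 7]) in severity, each with visit-level Gaussian noise.

Zeroing both latency effects yields a null cohort in which typing carries no
information about severity or group — the pipeline's AUC calibration check.
The noise scales were chosen once so that the two prescribed calibration
conditions are jointly coherent: the default 0.25-SD effect is recoverable
(LOGOCV AUC ≥ 0.70 for the NHPT target) while the zero-effect cohort scores
at chance. That places the severity effect, not idiosyncratic typing style,
as the dominant between-subject latency factor — a deliberate idealisation.

What the generator does **not** emulate, and what green tests therefore do
not show about real data: real typists differ far more from one another than
their disease state explains (idiosyncratic style, device, language,
autocorrect); latencies are not i.i.d. log-normal within a day (bursts,
fatigue, diurnal structure); key-class usage is language- and user-specific;
severity drifts within a year rather than staying fixed; and visit outcomes
have rater and learning effects. Performance numbers on this generator
characterise the pipeline's correctness and calibration, not expected
clinical accuracy.

## Problem sizes and numerical choices

The test-suite and acceptance-script runs use the full 126-subject default
cohort for the effect-recovery and null-calibration checks (five seeds each;
NHPT window $w_d = 4$, $\tau_d = 50$ events — the event-count threshold used
in earlier keystroke work — chosen so each LOGOCV fold trains on a few
thousand day-rows), 200 simulated cohorts for bootstrap-CI coverage at a
known true AUC of 0.75, ten seeds of 1,000×6 matrices for imputation
recovery at 20% missingness completely at random, and ten seeds of the
3-informative/7-noise benchmark (effect size d = 1.5, n = 200, five groups)
for RFE consensus recovery. Smaller "micro" cohorts (24 subjects, 100 days)
back the unit tests.

Other numerical decisions: z-score variance guard 1e-12, with feature
columns that are constant within a training fold (e.g. a saturated count)
dropped by a fold-level variance filter rather than erroring; imputer ridge
jitter 1e-8 on the normal equations for rank-deficiency; grid-search ties
resolved toward larger $\tau_d$ then smaller $w_d$; the exact
contingency-table test uses the probability-ordering two-sided rule (the
convention of standard exact-test implementations); the association test
(status ~ prediction + age + sex + ordinal education + daily keystroke
volume, all standardized) reports Wald p-values and falls back to a flagged
ridge-penalized IRLS refit under separation, which small cohorts do trigger;
no multiple-testing correction is applied, mirroring the source analyses,
and reports say so.

## Known limitations

* The exact membership of the composite clusters and the full daily
  statistic registry in the original work are not public; the defaults here
  are the documented hypothesis-driven reconstruction, and both are
  config-exposed rather than hard-coded.
* KNN has no native class-weighting; its votes are unweighted even when the
  rest of the ensemble trains balanced.
* The published headline AUCs were obtained on a restricted clinical cohort
  and are not reproducible from synthetic data; the acceptance machinery
  therefore validates calibration properties and worked contingency-table
  examples instead.
* Exact Shapley enumeration is exponential in the feature count and
  deliberately refuses more than 15 features.

## A minimal run

```{r, eval = FALSE}
cfg <- kd_cohort_config()
cohort <- kd_simulate_cohort(cfg, seed = 1)
daily <- kd_featurize(cohort$events)
spec <- kd_target_spec("nhpt", w_d = 4, tau_d = 50)
res <- kd_train_evaluate(daily, cohort$clinical, cohort$demographics, spec,
                         seed = 1)
res$cv_auc          # LOGOCV AUC in the training split
res$cv_ci           # grouped bootstrap 95% CI
res$holdout_metrics # sensitivity/specificity/accuracy/prevalence
```
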