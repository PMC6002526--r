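# feigndep

Mouse-tracking kinematics and symptom-endorsement analysis for detecting
feigned (malingered) depression.

## The problem

Depression is easy to feign and expensive when feigned: its symptoms are
intuitive, and self-report screening instruments can be coached against.
One countermeasure records *how* a respondent answers rather than what
they answer: in a double-choice task, the respondent clicks START at the
bottom of the screen, reads a yes/no question about depressive symptoms,
and moves the mouse to a YES or NO box in an upper corner while the cursor
path is logged. Lying is cognitively expensive — especially on *complex*
questions whose truthful answer is the conjunction of two propositions —
so deceptive responders hesitate, arc toward the suppressed alternative,
and over-endorse symptoms indiscriminately, while genuinely depressed
respondents are slowed by psychomotor retardation instead.

`feigndep` implements the complete analysis pipeline for this paradigm
across three conditions (truth-tellers, liars simulating depression,
depressed patients):

* **protocol** — the nine-category, 76-question stimulus set with
  conjunctive answer keys and the "more than five atypical symptoms"
  screening rule (`build_stimulus_set()`, `sims_af_flag()`);
* **synthetic cohorts** — a seeded generator emitting raw trajectory logs
  and endorsements whose *extracted* features are calibrated to the
  published group statistics (`generate_cohort()`, `default_profiles()`);
* **kinematics** — standardization to the tracker coordinate space,
  101-frame time normalization, and the per-trial metrics IT, RT, MD,
  MD-time, AUC, x/y-flips, velocity and acceleration
  (`trial_features()`);
* **features** — aggregation into the fixed 83-feature participant vector
  (`extract_features()`, `feature_schema()`);
* **statistics** — one-way ANOVA with omega-squared
  (`F = MS_b/MS_w`, `ω² = (SS_b − df_b·MS_w)/(SS_t + MS_w)`) and Tukey
  HSD contrasts (`anova_all()`, `tukey_hsd()`);
* **selection** — correlation-based feature selection with greedy
  stepwise search, merit `k·r̄_cf / √(k + k(k−1)·r̄_ff)`
  (`cfs_select()`), plus the study's fixed predictor sets
  (`named_subset()`);
* **classification** — native Gaussian naive Bayes, the interpretable
  two-rule tree (`2DS-c < 3.5 ⇒ truth-teller; else MD-time 2DS-d >
  4048 ms ⇒ depressed, else liar`), a depth-2 Gini tree, and adapters to
  SVM / random forest / multinomial logistic models, under stratified
  k-fold cross-validation and held-out evaluation (`kfold_cv()`,
  `evaluate_holdout()`, `printed_tree()`);
* **pipeline** — one-seed end-to-end orchestration writing plain-text
  artifacts (`run_pipeline()`).

## Worked example

```r
library(feigndep)

ss <- build_stimulus_set(seed = 1)
cohort <- generate_cohort(
  cohort_config(n_per_group = c(truth_teller = 6, liar = 6, depressed = 6),
                seed = 42),
  stimulus_set = ss
)
features <- extract_features(cohort)
group_summary(features, c("RT", "MD", "AUC", "2DS-c", "VAS"))
#>    feature group            n     mean       sd
#>  1 2DS-c   depressed        6    9.33    0.816
#>  2 2DS-c   liar             6   13.3     0.816
#>  3 2DS-c   truth_teller     6    1.33    0.816
#>  7 MD      depressed        6    0.496   0.0305
#>  8 MD      liar             6    0.569   0.0181
#>  9 MD      truth_teller     6    0.452   0.0286
#> 10 RT      depressed        6 6559.    331.
#> 11 RT      liar             6 4036.    119.
#> 12 RT      truth_teller     6 3936.    107.
#> 14 VAS     liar             6    7.67    1.75
#> 15 VAS     truth_teller     6    0.333   0.516
```

The group structure is the published one: liars endorse concordant complex
symptoms far beyond the 3.5 threshold and over-endorse atypical symptoms,
depressed patients are by far the slowest, and curvature (MD) orders
truth-tellers < depressed < liars.

```r
cfs_select(features)
#> <cfs_result> merit 0.8535; 2 feature(s): MD-time, v_x

kfold_cv(features, classifier_spec("gaussian_nb"), k = 6, seed = 1)
#> <cv_report> gaussian_nb, 6-fold CV: accuracy 100% (n = 18)

mean(printed_tree(features) == features$label) * 100
#> [1] 94.44444
```

On this small synthetic cohort the greedy selector needs only a latency
feature plus a velocity feature to saturate the merit, cross-validated
naive Bayes is perfect, and even the fixed two-rule tree recovers 94% of
labels. These numbers describe the *configured* group separation of the
generator — they are not evidence about human cohorts.

Full run with every artifact (feature tables, ANOVA/Tukey tables,
selection report, accuracy tables, average-trajectory figure, manifest):

```r
run_pipeline(pipeline_config(seed = 1), out_dir = "run1")
```

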