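---
title: "Detecting feigned depression from mouse dynamics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting feigned depression from mouse dynamics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Major depression is straightforward to feign: its symptoms are common
knowledge, and self-report screening instruments can be beaten by coaching.
A promising alternative is to watch *how* a respondent answers rather than
*what* they answer. In a double-choice computerized task, the respondent
presses a START button at the bottom of the screen, a yes/no question about
depressive symptoms appears, and the respondent clicks one of two response
boxes in the upper corners while the mouse trajectory is recorded. Lying
carries a measurable cognitive cost: deceptive responders initiate and
commit to a response differently, their cursor arcs further toward the
alternative they must suppress, and they over-endorse symptoms
indiscriminately — while genuinely depressed respondents are slowed by
psychomotor retardation rather than by cognitive load.

`feigndep` implements the complete analysis pipeline for this paradigm over
three experimental conditions: healthy **truth-tellers**, healthy
**liars** instructed to simulate depression, and clinically **depressed**
patients answering honestly. Because no raw recordings from the original
study are deposited anywhere, the package pairs the analysis code with a
seeded synthetic-cohort generator calibrated to the study's published group
statistics, so that every stage of the pipeline can be exercised, tested
and benchmarked end to end.

# The stimulus protocol

The question set has nine categories. Simple items carry one proposition:
control statements about the experimental situation (`EX`, 5 items),
typical depressive symptoms (`DS`, 10), and very atypical symptoms (`VAS`,
15, drawn from an atypical-symptom screening scale whose rule flags a
respondent endorsing more than five of them). Complex items carry two
propositions and are keyed "yes" only when *both* are true: concordant and
discordant symptom pairs (`2DS-c`, `2DS-d`, 15 each), symptom-plus-control
pairs (`DS&EX-c`, `DS&EX-d`, 5 each) and control pairs (`2EX-c`, `2EX-d`,
3 each) — 76 questions in all, 30 simple and 46 complex. Conjunctions are
the load-bearing design idea: a liar must check each proposition against a
maintained false self-model, so complex questions amplify the deceptive
cost.

`question_categories()` encodes the categories and their truthful answer
keys for healthy and depressed respondents; the keys are derived from the
conjunction semantics rather than hard-coded. (The source description of
expected yes/no tallies is internally inconsistent with a 76-item set;
deriving keys from the component propositions is the only reading that
adds up, and gives 8 truthful "yes" answers for a healthy respondent and
38 for a depressed one.)

# The synthetic cohort generator

## What is calibrated

Each condition is described by a `group_profile()`: endorsement
probabilities per symptom category, control-question error probabilities,
and kinematic targets. The kinematic targets are the published group means
and standard deviations — reaction time (4018.79 / 6641.81 / 4030.60 ms
for truth-tellers / depressed / liars), initiation time, the latency of
the maximum deviation as a fraction of RT, maximum deviation (0.44 / 0.51
/ 0.57), area under the curve (1.01 / 1.09 / 1.25) and x/y flip counts.
Only pairwise group *differences* in endorsement counts are published, so
absolute anchors had to be chosen once: truth-tellers average 1.0 endorsed
`DS` items, 1.5 `2DS-c`, 0.5 `VAS`, 0.5 `DS&EX-c` and 6.0 `2DS-d`; the
other groups follow from the published differences. These anchors respect
every published difference, keep truth-tellers below the interpretable
tree's 3.5-symptom threshold on `2DS-c` with the other groups above it,
and push the median liar past the atypical-symptom screening cut-off. The
`2DS-d` direction (truth-tellers *higher*) follows the published sign
pattern even though it is surprising under naive conjunction semantics; it
is a free calibration direction here.

RT, IT and the per-trial maximum deviation are drawn from lognormal
distributions moment-matched to the target mean/SD — the natural choice
for strictly positive, right-skewed latencies when only two moments are
given. The per-trial AUC target is coupled proportionally to the MD draw
(`auc = auc_mean * md / md_mean`), which keeps both cohort means on target
with a single spatial scale draw and reproduces the positive MD–AUC
correlation real paths show.

## Why the trajectories contain a regressive loop

A single-pass path bounded by a maximum perpendicular deviation `MD` can
enclose at most `MD × L` of area against an ideal line of length `L`. In
the standardized space the line is ~1.6–1.8 units long, so the published
MD/AUC pairs (e.g. 0.44 / 1.01) are *geometrically impossible* for any
path that only sweeps forward: the implied areas exceed the single-pass
bound for all three groups. Real cursor paths achieve such areas by
backtracking — hesitating, drifting back toward the start, and sweeping
regions twice. The generator therefore builds each movement as:

1. a smooth start-to-box baseline with a perpendicular **deviation bump**
   whose peak amplitude is the trial's MD draw and whose peak frame is
   placed at the MD-latency target;
2. one **regressive loop** — a closed excursion (along-line amplitude up
   to ~0.5 units, two windings) inserted mid-path whose swept signed area
   tops the AUC up to its target, iteratively rescaled against the
   package's own area extractor; the loop's perpendicular span is capped
   so that the global deviation argmax provably stays at the bump peak;
3. **micro-reversals** (small step reflections, plus at most one terminal
   overshoot) inserted at spaced frames until the per-axis flip counts
   equal the trial's flip draws.

The movement phase is emitted on the 101-point equal-time grid, with the
pre-movement idle phase sampled at the configured rate (default 70 Hz).
Time normalization of such a log is an exact identity, so every
constructed feature survives extraction bit-for-bit and cohort means of
extracted features are unbiased estimators of the configured targets.
This is a deliberately feature-targeted generative model, not a
cognitive-process model: its contract is the joint distribution of the
extracted features, nothing more.

## Click points and vertical velocity

Clicks land inside the response box but not at its centre: the normalized
click ordinate is drawn around 1.326 (just inside the box's lower edge),
which pins the mean per-frame vertical velocity near 0.0133 normalized
units/frame, as observed; the abscissa magnitude is drawn around 0.96.
Because the horizontal velocity of a mirrored path is nearly constant by
construction, per-frame velocities are computed on the *unmirrored*
coordinates, so a participant's yes/no response mix (and hence their
group) shows up in the sign and magnitude of the mean horizontal velocity.

## What the generator does not emulate

No learning or fatigue across trials, no question-difficulty gradients
within a category, no within-participant kinematic consistency beyond the
group profile, no practice trials, and no depression-severity covariates.
Passing tests on synthetic cohorts therefore demonstrates that the
*pipeline* is correct and that the configured group structure is
recoverable — not that the published human classification accuracies
would replicate; those were measured on undeposited human data and are
out of reach by construction.

# Kinematic standardization and metrics

Raw pixel paths are affinely remapped so the start button sits at the
origin and the response-box centres at (−1, 1.5) and (1, 1.5); right-box
trials are mirrored about x = 0, so every standardized path moves leftward
(the convention of the tracker family this space imitates). The movement
phase — from the last sample still at the start position to the click —
is resampled to 101 equally spaced time frames by linear interpolation.

Per-trial metrics (returned by `trial_features()`):

* **IT** — time to the first displacement; the movement-onset threshold
  ε defaults to 0 px (first coordinate change) and is configurable;
* **RT** — time from question onset to the click;
* **MD** — the largest perpendicular distance between the path and the
  straight line joining its endpoints, *signed* positive toward the
  non-chosen box (published group values are positive, consistent with
  net attraction toward the alternative);
* **MD-time** — the latency of that frame, reported on the question-onset
  clock (so it includes IT; group MD-time means sit near 0.6 × RT, which
  is only consistent with a question-onset clock);
* **AUC** — the signed shoelace area of the closed polygon formed by the
  path and the reversed ideal segment; backtracking regions count with
  multiplicity, which is what lets AUC exceed the naive MD × L bound;
* **x-flip / y-flip** — sign reversals of successive non-zero per-frame
  increments (zero increments are skipped);
* **v_x, v_y, a_x, a_y** — signed means of the per-frame increments (100
  values) and their differences (99 values); an absolute-mean variant is
  available behind a switch since the original convention is unstated.

Degenerate paths (coincident endpoints) are rejected; samples outside the
screen are clamped with a warning.

# The 83-feature participant vector

The schema is the unique reading of the published feature enumeration in
which every feature name used anywhere in the analysis exists and the
total is 83: the seven metrics averaged overall and within each of the
nine categories (70), the four overall velocity/acceleration means, six
symptom-endorsement counts (`DS`, `2DS-d`, `2DS-c`, `DS&EX-d`, `DS&EX-c`,
`VAS`) and three control-error counts (`EX`, `2EX-d`, `2EX-c`).
Per-category velocities are excluded — including them breaks the count.
Trials dropped for degeneracy are removed from means with a warning;
counts are unaffected. The per-category means reconstruct the overall
mean exactly when weighted by item counts, which the tests assert as an
algebraic invariant.

# Univariate statistics

`oneway_anova()` is a direct sums-of-squares implementation reporting
`F = MS_between / MS_within` and the omega-squared effect size
`(SS_b − df_b·MS_w) / (SS_t + MS_w)`, clamped below at zero with a flag
(the unbiased estimator can go negative under the null). The published
effect-size column labelled omega-squared reaches 0.87, which is
ambiguous between ω and ω²; this package always reports ω² and does not
attempt to match those printed values. `tukey_hsd()` reports the mean
difference, the studentized-range statistic `q` with its adjusted p value
from `ptukey`, and a pooled-variance t-style statistic (`q/√2`) matching
the *kind* of statistic printed in the published pairwise tables; the
exact post hoc formula behind those tables is unstated, so the value is
matched in kind, not numerically. `transitivity_check()` verifies that
three pairwise differences close algebraically — the published `DS`,
`2DS-c` and `VAS` rows do.

# Feature selection

`cfs_select()` implements Hall's correlation-based feature selection:
subset merit `k·r̄_cf / sqrt(k + k(k−1)·r̄_ff)` with greedy forward
search and deterministic schema-order tie-breaking. The class correlation
of a feature is the signed point-biserial correlation for two-level
labels; for the three-level label, where no signed ordering exists, it is
the mean absolute one-vs-rest point-biserial (a symmetric-uncertainty
variant was considered and rejected as needlessly discretization-
dependent for these continuous features). Note a formula fact the tests
pin down: a subset consisting only of exact duplicates of one feature has
merit exactly equal to the single feature (the `k(k−1)` redundancy term
cancels the numerator's growth), so duplication never helps but only
strictly hurts once the subset carries more than one distinct signal.
The four fixed predictor sets used by the published models
(`named_subset()`) are carried verbatim: the 6-feature three-class CFS
selection, the 14-feature two-class selection, the five most
class-correlated features, and the 16 features restricted to complex
depressive questions.

# Classification and evaluation

Three classifiers are authored natively, because they carry the
interpretable content: Gaussian naive Bayes (relative-frequency priors,
per-class feature mean/variance with a floored-variance guard), the fixed
**two-rule tree** — fewer than 3.5 endorsed `2DS-c` symptoms ⇒
truth-teller; otherwise mean `MD-time 2DS-d` above 4048 ms ⇒ depressed,
else liar; thresholds strict, boundary values fall to the "else" branch —
and a depth-2 Gini tree trainer (midpoint thresholds, majority leaves)
whose learned structure can be compared with the fixed tree. The
remaining models are adapters to standard implementations: a linear SVM
(`e1071`, the SMO family), `randomForest`, and multinomial logistic
regression (`nnet`) standing in for the logistic-model-tree family.
Re-implementing these algorithms is outside the package's contribution.

Cross-validation is stratified by class (so a 60-participant cohort gives
ten folds of six, two per class; an unstratified switch exists since the
original partitioning discipline is unstated) and deterministic given its
seed. A diagnostic "memorizer" classifier — perfect recall of training
rows, majority class otherwise — is included purely to prove the folds do
not leak: it scores 100% when test = train and collapses to the base rate
under cross-validation. Two-class mode drops truth-tellers from training
and scoring, giving 2×2 confusion matrices over 40 (training) or 18
(held-out) participants; the published two-class test-set header's n = 28
is inconsistent with the cohort arithmetic (27 participants, 18 after
excluding truth-tellers), and the arithmetic wins here.

# Numerical choices and problem sizes

Bisection on the bump-width parameter (40 iterations on κ ∈ [3, 500])
matches the base-path area when the AUC draw falls below the bump's
default area; the loop amplitude is refined by three measured rescalings
(relative area error typically < 1e−3). Flip insertion recounts after
every notch and gives up gracefully when a draw is unreachable (realized
counts then exceed the draw only when the loop itself already produced
more reversals — reversals cannot be removed). Ties in greedy selection
and in `which.max`-based arg-maxes resolve to the first (schema-order)
candidate.

The validation suite uses cohort sizes matching the study protocol
(60-participant training cohorts, 27-participant held-out cohorts),
500 trials per group for kinematic parameter recovery at three standard
errors, 150 participants per group for endorsement recovery, and 100
label permutations for the chance-level check — sizes chosen to make the
statistical assertions sharp while keeping a full run in a few minutes on
one core.

# Known limitations

* The generator's feature-space realism is exactly as deep as its
  calibration: trajectories look like plausible hesitant cursor paths but
  encode no cognitive dynamics; classifier accuracies on synthetic
  cohorts reflect the configured group separation, not human
  separability.
* Absolute endorsement anchors are a modelling choice pinned only by
  published differences and thresholds.
* The `2DS-d` sign pattern is reproduced, not explained.
* Real tracker log formats are not parsed; the raw-CSV dialect is the
  package's own.
* Omega-squared values and post hoc t values from the original tables are
  matched in kind but deliberately not in value; no raw data exists to
  compare against.
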