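---
title: "Propensity-triplet randomization and rerandomization inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Propensity-triplet randomization and rerandomization inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(tripletrct)
```

`tripletrct` implements the design and analysis of a three-arm
individually randomized trial of SMS reminders for motorcycle-taxi
helmet use: a control arm and two message framings ("fear" appeals and
"social-norm" appeals), with consistent helmet wearing at week 6 as the
binary endpoint. This vignette documents the statistical methods, the
package's numerical choices, and the synthetic-data generator used to
validate them.

## 1. Design: propensity-score triplet randomization

Participants are randomized in matched triplets rather than by
independent coin flips, so that the three arms are balanced on the
strongest prognostic factor — baseline helmet habit — and on measured
covariates.

The procedure, implemented by `randomize_trial()`, is:

1. **Propensity model.** `fit_propensity()` fits a logistic regression
   of baseline consistent wearing on the chosen covariates
   (`default_covariates()` by default). Missing covariate values are
   imputed with the mode (categorical) or median (numeric), and the
   imputation values are stored in the model so that scoring new data
   is reproducible. Complete separation is detected (fitted
   probabilities within $10^{-7}$ of 0 or 1) and flagged.
2. **Stratification.** `stratify()` splits the roster by
   `baseline_consistent`, since adherent and non-adherent drivers have
   very different week-6 outcome distributions.
3. **Triplet matching.** Within each stratum, `make_triplets()` sorts
   participants by propensity score (a stable sort, so ties preserve
   roster order) and groups consecutive runs of three. When the stratum
   size is not divisible by three, the one or two highest-scoring
   participants form a `leftover` group.
4. **Assignment.** For each triplet, `assign_arms()` draws one of the
   $3! = 6$ orderings of (control, fear, social) uniformly; the
   triplet's members take the arms in that order. Leftover participants
   take the first position(s) of their drawn ordering. With strata of
   207 and 184, this yields 69 + 61 triplets and one leftover, and arm
   sizes {130, 130, 131}.

Because each complete triplet contributes exactly one participant per
arm, any within-triplet confounder is balanced by construction, and the
assignment distribution is known exactly — the basis for the inference
below.

## 2. Estimation

All effect measures are computed at the participant level by
`arm_comparison()`:

- **Odds ratio.** For a contrast of arm $E$ versus arm $R$ with
  event counts $a/(a+b)$ and $c/(c+d)$, the odds ratio is $ad/(bc)$,
  computed on the log scale as
  $\log a + \log d - \log b - \log c$ so that empty cells propagate to
  $0$, $\infty$, or `NaN` transparently rather than erroring. The same
  quantity is available by maximum likelihood through
  `fit_logistic()` (IRLS via `stats::glm`, treatment coding forced for
  every factor including the ordered frequency scales, convergence
  tolerance $10^{-8}$); the two routes agree to numerical precision
  and are cross-checked in the test-suite.
- **Risk difference** (`risk_difference()`): difference in percentage
  points, computed from unrounded proportions.
- **Difference in differences** (`difference_in_differences()`): the
  change in an arm's percentage-point lead over control between
  baseline and week 6.
- **Ratio of odds ratios** (`ratio_of_odds_ratios()`): the
  effect-modification measure — the contrast's odds ratio among
  baseline always-wearers divided by the same contrast's odds ratio
  among baseline inconsistent wearers.

Comparisons are estimated in three analysis populations: all
observations, the baseline-consistent stratum ("maintenance of
adherence"), and the baseline-inconsistent stratum ("promotion of
adherence"). Covariate-adjusted estimates (`adjusted = TRUE`) take the
arm coefficient from a logistic model with the adjustment covariates
(`default_adjustment()`), restricted to complete cases with the dropped
count reported.

## 3. Randomization inference

Asymptotic standard errors are unreliable here: outcomes are binary,
strata are moderate, and the assignment mechanism is a matched-triplet
draw rather than independent sampling. `permutation_test()` therefore
uses the design itself as the reference distribution:

1. The observed statistic $T_{\mathrm{obs}}$ (default: the log odds
   ratio of the contrast) is computed on the analyzed subset.
2. For each of $B$ replicates, every triplet independently redraws one
   of its 6 arm orderings — exactly the distribution the actual
   randomization used — and the statistic is recomputed on the units
   with observed outcomes under the new labels. Missingness stays with
   the participant, so the permuted analysis sets vary as they would
   have under a different realized assignment.
3. The one-sided p-value is the plain fraction
   $\#\{T_b \ge T_{\mathrm{obs}}\}/B$; the two-sided p-value uses
   $|T_b| \ge |T_{\mathrm{obs}}|$. The `p_method = "plus_one"` option
   gives the finite-sample-valid $( \#\{\cdot\} + 1)/(B + 1)$ variant;
   the plain fraction is the default because it is the conventional
   Monte-Carlo estimate of the exact permutation p-value and is what
   the exhaustive-enumeration checks target.

Numerical edge cases are handled explicitly rather than silently:

- A permuted table with an empty cell yields $\pm\infty$ or `NaN`. An
  undefined (`NaN`) statistic is counted as an exceedance — the
  conservative choice — but if more than 10% of replicates are
  undefined the test aborts, since the contrast is then too sparse for
  this statistic.
- A constant analyzed outcome short-circuits to $p = 1$: no relabeling
  can move the statistic.
- One-sided tests are only accepted for intervention-versus-control
  contrasts, where the registered hypothesis is directional; the
  head-to-head framing contrast is two-sided.

Default $B$ is 10,000 (5,000 for the covariate-adjusted statistic,
which refits a `glm` per replicate). These defaults give a Monte-Carlo
standard error below 0.005 for p-values near 0.05, and are this
package's own choices of problem size.

The engine is validated against exhaustive enumeration: for $U$
triplets there are exactly $6^U$ equally likely joint assignments, and
for small $U$ the test-suite enumerates all of them with an independent
implementation and checks the Monte-Carlo p-value to within three
binomial standard errors.

**Effect modification** (`effect_modification_test()`) applies the same
machinery to the log ratio of odds ratios between baseline strata,
two-sided.

**Multiplicity.** The trial's primary registered outcome is the joint
test of the three all-observations comparisons. `holm_bonferroni()`
applies the step-down rule: order the $m$ p-values, compare the
$k$-th smallest to $\alpha/(m-k+1)$, and stop at the first failure.
Adjusted p-values agree with `stats::p.adjust(method = "holm")`.

## 4. Balance diagnostics

`balance_table()` reproduces the conventional Table-1 diagnostics:
Pearson chi-square tests without continuity correction for categorical
and binary variables (`chisq_balance()`), and one-way ANOVA for age and
household size (`anova_oneway()`). Each row uses that variable's
complete cases, so denominators vary with item missingness exactly as
in the source tables. Under triplet randomization these tests are
descriptive, not confirmatory — imbalance beyond chance is a coding
error, not bad luck — and the test-suite checks that their null
rejection rate is nominal on simulated trials.

## 5. The synthetic-data generator

`simulate_trial()` + `apply_effects()` (or the wrapper
`simulate_assigned_trial()`) generate participant-level trials with the
structure the analysis assumes. Defaults are calibrated to the study
conditions and are *fixed* — tests and acceptance checks run against
them as-is:

- 391 participants; baseline consistent-wearing probability 0.53.
- Covariates drawn independently from the pooled study marginals
  (`default_marginals()`), with per-variable item missingness matching
  the study's denominators (`default_covariate_missingness()`).
- Week-6 outcome probability in the control arm: 2/3 for baseline
  always-wearers and 0.36 for baseline inconsistent wearers, on the
  logit scale. Arm effects are per-arm, per-stratum log-odds shifts
  added to these baselines.
- Week 3 applies a configurable fraction of the week-6 effect
  (`week3_effect_fraction`, default 0.5). The attenuation is not
  quantified in the source setting — group differences were visible at
  6 weeks but not at 3 — so 0.5 is an explicit placeholder, exposed in
  the configuration.
- Per-wave attrition of 0.10 (week 3) and 0.12 (week 6), independent of
  outcome by default (an arm-named attrition vector enables
  differential attrition). This reproduces the 391 → ~352 → ~344
  analyzable-denominator pattern, with roughly 110–118 analyzable
  participants per arm at week 6.
- `covariate_link` (default 0) optionally ties night/speeding driving
  frequency to baseline adherence, so the propensity model can be
  exercised with real signal; by default covariates are independent of
  outcome and the propensity score is flat.

Deliberate simplifications: no habit-formation dynamics beyond the
two-wave transition model, no message-content modeling, and no
social-desirability misreporting (discussed but not quantified in the
source setting).

### Non-collapsibility and parameter recovery

The generator applies effects *conditionally* on baseline stratum. The
odds ratio is not collapsible: a conditional log-odds shift of
$\ln 1.58$ in both strata produces a *marginal* (pooled two-by-two)
odds ratio of about 1.51, with no confounding involved. Parameter
recovery is therefore assessed with the correctly specified model — a
logistic regression of the week-6 outcome on arm *and* the baseline
stratum indicator — and on the log-odds scale, since the mean of raw
odds ratios across replicates is Jensen-biased upward. The acceptance
checks confirm that the mean conditional log odds ratio over 300
replicate trials at $n = 391$ is within Monte-Carlo error of
$\ln 1.58$.

## 6. Orchestration and reproducibility

`run_full_analysis()` produces the full table set from any assigned
roster: balance rows, adherence proportions by wave and arm with
differences from control and the week-6 difference in differences, the
3-contrast × 3-subgroup odds-ratio grid with permutation p-values
(one-sided against control, two-sided head-to-head), the
effect-modification row, and the Holm decisions for the primary family.
Every permutation test takes a sub-seed derived deterministically from
the report seed, so identical seeds give byte-identical JSON via
`report_json()`.

`fixture_roster()` reconstructs a minimal participant-level roster
(arm, stratum, outcomes) from the packaged aggregate count tables; it
reproduces every unadjusted estimate exactly. Its triplet structure is
synthetic — the true triplet composition is not recoverable from
aggregates — so permutation p-values computed on it are approximate and
labeled as such; `shuffle_seed` breaks the block ordering when a less
structured roster is wanted.

## 7. Limitations

- Permutation p-values on the fixture roster are approximate (see
  above); exact reproduction of the published p-values requires the
  realized triplet structure.
- The covariate-adjusted permutation test refits a logistic model per
  replicate and is correspondingly slower; its default $B$ is halved.
- The generator draws the two waves' outcomes independently given arm
  and stratum; within-participant correlation across waves is not
  modeled.
- The sparse-contrast abort threshold (10% undefined replicates) is a
  package choice; contrasts near that boundary deserve a larger-sample
  design, not a different threshold.
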