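---
title: "Honest forests for heterogeneous effects in lottery designs: models, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Honest forests for heterogeneous effects in lottery designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hforest)
```

This vignette is the package's own account of its statistical machinery: the
estimands and the forest model, every tunable parameter and its default, what
the synthetic-data generator does and does not emulate, the numerical and
design choices made where the design was genuinely open, and the known
limitations.

## 1. Setting and estimands

The data model is a household-randomized insurance lottery: households on a
waiting list are selected with probability `p_select` (all members
together); selected individuals may apply for coverage, applications may be
approved, and enrollment `D` results; a small fraction of non-selected
controls obtain coverage anyway.  For each person we observe lottery
selection `Z`, enrollment `D`, the funnel flags, baseline covariates `X`,
survey weights `w` and a household identifier, plus outcomes `Y`.

Three aggregations of the individual effect `tau_i = Y_i(1) - Y_i(0)` are
estimated: the average treatment effect `ATE = E[tau]`, the conditional
average `CATE(x) = E[tau | X = x]`, and prespecified-subgroup averages
`GATE(g) = E[tau | G = g]`.  Intent-to-treat analyses treat `Z` as the
treatment; instrumental analyses target the effect of `D` among compliers,
using `Z` as the instrument.

## 2. The honest causal forest

Writing the observed outcome as `Y = mu(X) + Z tau(X) + error`, the
conditional mean is `m(x) = mu(x) + e(x) tau(x)` with `e(x) = P(Z=1|X=x)`.
Estimation is a two-step, Robinson-style orthogonalization:

1. **Nuisances.** `m` and `e` are fit by honest regression forests
   (regressing `Y` and `Z` on `X`) and evaluated *out of bag*: the
   prediction for person `i` aggregates only trees whose household-level
   subsample excluded `i`'s household.  Propensities are clamped to
   `[0.01, 0.99]` — clamping rather than dropping preserves the randomized
   design, where `e` is essentially constant by construction.
2. **Trees on centered data.** Honest causal trees are grown on
   `(Y - m_hat, Z - e_hat)`.  Each tree draws a household-level subsample
   (fraction `sample_fraction`), splits it into a splitting half and an
   estimation half (households, again, move as units), chooses splits
   greedily on the splitting half, and re-estimates every leaf effect on the
   estimation half as the weighted residual-on-residual ratio
   `sum(w (Y - m)(Z - e)) / sum(w (Z - e)^2)`.

**The split criterion.** Among `mtry` randomly drawn covariates and all
candidate thresholds (midpoints between consecutive distinct splitting-half
values; `0.5` for binary covariates), the chosen split maximizes the gain in

```
crit(node) = n_node * tau_hat_node^2 / N_tr
           - (1/N_tr + 1/N_est) * (S2_treated / p + S2_control / (1 - p))
```

summed over the would-be children, where `N_tr`/`N_est` are the tree-level
half sizes, `p` is the node's treated share and `S2` are within-node
variances of the centered outcome by arm.  The first term rewards
between-leaf effect heterogeneity, the second penalizes noisy leaves.  A
node stays a leaf when no admissible candidate strictly improves the
criterion.

Conventions that the printed form of the criterion leaves open, fixed here
once:

- *Survey weights* enter every within-leaf estimator, variance and treated
  share; the outer `1/N` counts stay unweighted person counts.  (The
  analysis is weighted throughout; the counts are the printed form.)
- *The treated share `p`* is the node-level (not sample-level) weighted
  share.
- *The variance penalty* is summed per leaf without leaf-size weighting,
  i.e. the criterion is implemented exactly as written rather than as any
  of its weighted variants.
- *Ties* are broken toward the lowest covariate index, then the lowest
  threshold — determinism over elegance.
- *Admissibility*: each side of a split must hold at least
  `alpha_imbalance` of the node's splitting-half observations, at least one
  treated and one control splitting-half observation, and at least
  `min_node_size` treated **and** control estimation-half observations
  (total count for regression forests).
- *Degenerate leaves*: an estimation-half leaf whose centered-treatment
  second moment vanishes inherits its parent's estimate and is flagged.

**Prediction** uses the adaptive locally weighted estimator: each tree
contributes kernel weight `1/|leaf|` to the estimation-half members of the
leaf containing the query point, and

```
tau_hat(x) = sum_i a_i(x) w_i (Y_i - m_i)(Z_i - e_i)
           / sum_i a_i(x) w_i (Z_i - e_i)^2 .
```

Out-of-bag predictions exclude trees containing the query person's
household; a person covered by every tree receives a flagged `NA` rather
than a silently biased value.  The instrumental forest replaces the
denominator by the centered first-stage cross-moment
`sum a w (Z - z_hat)(D - d_hat)` and centers `Y`, `D` and `Z` each by its
own nuisance forest; the instrument and treatment nuisance fits share one
seed stream so that perfect compliance (`D` identical to `Z`) reduces the
estimator *exactly* to the causal forest.

### Hyperparameters

| parameter | default | meaning |
|---|---|---|
| `n_trees` | 2,000 | ensemble size; controls only Monte-Carlo noise.  Production-scale analyses of this design use 20,000; tests and the acceptance script use 100–500, stated per experiment. |
| `sample_fraction` | 0.5 | household fraction subsampled per tree (without replacement) |
| `honesty_fraction` | 0.5 | share of each subsample used for split search |
| `mtry` | `ceil(sqrt(p))` | covariates tried per split.  Deliberately conservative; with few covariates, `mtry = p` markedly reduces shrinkage of subgroup contrasts and is used in the recovery experiments. |
| `min_node_size` | 5 | minimum treated and control estimation-half count per leaf |
| `alpha_imbalance` | 0.05 | minimum per-side share of a node's splitting-half observations |
| `imbalance_penalty` | 0 | optional penalty `* (1/n_L + 1/n_R)` on the gain |

`tune_hyperparameters()` draws random candidates from documented ranges
(sample fraction 0.25–0.70, honesty fraction 0.40–0.70, `mtry` 1–p, node
size 5–50 log-uniform, alpha 0.01–0.25, penalty 0–2), scores each — and the
defaults — by the survey-weighted out-of-bag R-loss
`mean(0.5 (Y - m - tau_hat (Z - e))^2)` of a small forest, and returns the
minimizer; because the defaults are always a candidate, tuning can never
degrade the objective.  The desk-scale budget is 50 draws of 200-tree
forests; the production protocol (thousands of draws, hundreds of trees,
documented in `tuning_budget()`) is a configuration away.

## 3. Aggregation: AIPW scores, clustering, weights

Per-person doubly robust scores are

```
gamma_i = m(X_i,1) - m(X_i,0)
        + (Y_i - m(X_i, Z_i)) (Z_i - e_i) / (e_i (1 - e_i)),
```

with the arm means built from the marginal-mean identity
`m(x,1) = m + (1-e) tau`, `m(x,0) = m - e tau` using out-of-bag nuisances
and CATEs.  The ATE is the survey-weighted score mean; its standard error is
the household-sum sandwich `sqrt(sum_h u_h^2) / sum w` with
`u_h = sum_{i in h} w_i (gamma_i - estimate)` — no small-sample degrees-of-
freedom correction, and 95% intervals use the normal quantile 1.96,
matching the symmetric intervals such analyses report.  GATEs are the same
average over a subgroup mask; by construction, subgroup estimates over any
partition recombine (weight-share-weighted) to the ATE exactly, and the
test suite asserts this identity at `1e-10`.

The complier effect is the ratio of the outcome score mean to the
first-stage (enrollment) score mean, with a delta-method SE from the
household-clustered covariance of the paired score sums; first stages below
`1e-6` raise a weak-instrument error rather than returning a nonsense
ratio.  No multiplicity correction is applied to the subgroup tables; the
run manifest records how many intent-to-treat tests would survive a
Bonferroni correction, as documentation only.

## 4. Heterogeneity diagnostics

**Calibration.** `calibration_test()` regresses the centered outcome on the
two constructed regressors `(Z - e) tau_bar` and
`(Z - e)(tau_hat_oob - tau_bar)` (survey-weighted, no intercept,
cluster-robust).  A mean-prediction coefficient `alpha` near one says the
average effect is well captured; a positive differential coefficient `beta`
is evidence of real, captured heterogeneity (one-sided p).  This plug-in
construction is the standard forest diagnostic, but it is **conservative
when the true effect is exactly homogeneous**: the estimated mean CATE
couples each observation's own noise negatively into its regressor, and in
simulations the null rejection rate is near zero.  We verified the
mechanism directly — substituting synthetic CATE noise independent of the
data restores a standard normal null.  `calibration_test_crossfit()`
therefore implements the same regression with household-level two-fold
cross-fitting: each fold's regressors (nuisances, CATEs and their mean) come
entirely from a forest fit on the other fold, each fold's regression is
internally valid, and the two one-sided p-values are combined by Bonferroni,
which bounds the level under the folds' dependence.  Measured on 100
homogeneous replicates the cross-fitted test rejects at 5%, with full power
against a strong two-group alternative.  The plug-in variant remains the
cheap default diagnostic inside `run_analysis()`; formal type-I control
should use the cross-fitted variant.

**TOC / RATE.** `toc_curve()` ranks people by a priority score and plots,
for each treated fraction `q`, the weighted mean AIPW score of the top-`q`
group minus the overall mean; the RATE is the trapezoidal integral over the
`q` grid (AUTOC weighting by default, Qini by flag; 100 evenly spaced grid
points).  Tied priorities carry no ranking information, so a cut inside a
tied block is prorated (each member replaced by the block's weighted mean) —
this makes a constant priority give an identically zero curve, which a
stable-order tie break would not.  `rate_with_se()` repeats a household-level
half-split protocol — fit on one half, rank the other half by predicted
CATEs, evaluate on the held-out half's own AIPW scores — and reports the
mean rate with the empirical standard error of that mean across splits;
splits overlap, so this SE is an honest description of split-to-split
variability rather than an exact sampling SE.

## 5. The synthetic-data generator

`dgp_config()` describes a full world; `generate_sample()` draws from it
deterministically.  What it emulates: household-level randomization (and
hence a real need for cluster-robust inference), 19 baseline covariate
columns with prevalences modelled on the in-person lottery sample (56%
female, 69% white, 34% with depression, ...; race drawn categorically with
an independent other-race flag, since only marginals are published),
covariate-dependent application (~64% of the selected) and approval (~48%
of applicants), ~2% control crossover, lognormal survey weights normalized
to mean one, three outcome families (gaussian component scores, Poisson
utilization counts, zero-inflated-lognormal spending), and configurable
effect heterogeneity (constant, linear, or step in a named covariate)
acting through selection or through enrollment.

Two deliberate simplifications: covariates are drawn independently across
persons and columns (real baseline tables have correlation structure the
publications do not report), and treatment effects are *additive on the
outcome mean* in every family, so that the true ATE equals the mean of
`tau(X)` exactly and recovery experiments have a closed-form truth.  Count
and spending effects in real data are closer to multiplicative; passing
tests on this generator therefore demonstrates correctness of the
estimators under the stated model, not robustness to misspecified outcome
families.  Survey non-response, wave structure, and the real lottery's
eight draws are not emulated.

Every generation stage draws from its own seed substream (a deterministic
hash of the root seed and the stage name), so adding an outcome or a
covariate never perturbs the other draws, and identical `(config, seed)`
reproduce byte-identical samples.

## 6. Numerical and design choices

- **Centering target.** The outcome is centered by the *marginal mean*
  forest `m(x)` everywhere (splitting, prediction, scores), the standard
  orthogonalization; a separate conditional-mean forest is not maintained.
- **Degenerate inputs.** Constant covariates yield single-leaf trees (not
  errors); splitless forests report uniform variable importance with a
  warning; missing values are rejected at validation rather than imputed;
  rows without out-of-bag nuisances are dropped with a logged count.
- **Exact greedy search.** The split criterion is maximized exactly at
  every node (the brute-force-verifiable form), not by a gradient
  approximation; the test suite checks equality against an independent
  exhaustive-search oracle on hundreds of random small instances.
- **Variable importance** is the depth-decayed split-count share
  (`d^-2`, depths 1–4), normalized to sum to one; the two-stage fit retains
  covariates whose importance exceeds 20% of the mean importance and refits
  nuisances and trees on the retained set for internal consistency.
- **Problem sizes.** The statistical experiments in the test suite and
  acceptance script state their sizes explicitly — e.g. recovery and
  coverage at ~4,000 persons in 3,200 households with 500-tree forests over
  100–200 replicates; calibration type-I error at ~900 persons over 100–200
  replicates — chosen as the smallest sizes at which the asymptotic
  behavior under test is visibly established.

## 7. Known limitations

- Per-point CATE confidence intervals (e.g. bootstrap of little bags) are
  not implemented; inference flows exclusively through AIPW score averages
  for populations and subgroups.
- The instrumental forest assumes no essential heterogeneity (no selection
  into enrollment on anticipated gains) and inherits the usual power loss
  of IV analyses; its subgroup intervals are wide at realistic sizes.
- The plug-in calibration test is conservative under exact homogeneity
  (Section 4); use the cross-fitted variant when the type-I error matters.
- Forests reject missing covariates rather than handling them in-tree;
  multi-valued or continuous treatments and survival outcomes are out of
  scope.
- Reproducing the published full-scale analyses requires the
  restricted-distribution person-level files and 20,000-tree fits; the
  package's experiments run on its own synthetic worlds.
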