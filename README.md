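# hforest

Honest causal forests and instrumental forests for heterogeneous treatment
effects in lottery-design experiments with imperfect compliance.

## The problem

In a randomized insurance lottery (the motivating design is the Oregon
Health Insurance Experiment: households on a waiting list are selected by
lottery, selected individuals may apply for coverage, and applications may
be approved), randomization identifies the effect of *being selected*, but
selection only translates into coverage through an application and approval
funnel, and the interesting policy questions are heterogeneous: *who*
enrolls, and *for whom* does selection or coverage change health, health-care
use and out-of-pocket spending?

`hforest` estimates, for a person-level sample with a binary instrument Z
(lottery selection), binary treatment D (enrollment), baseline covariates X,
survey weights and household clustering:

- **Individualized effects** (CATEs) `tau(x) = E[Y(1) - Y(0) | X = x]` by an
  honest causal forest: nuisance functions — the marginal outcome mean
  `m(x)` and the propensity `e(x) = P(Z = 1 | X = x)` — are fit by honest
  regression forests and evaluated out-of-bag; trees are then grown on the
  locally centered data `(Y - m, Z - e)`, choosing each split to maximize
  the negative expected-MSE criterion

  ```
  crit = (1/N_tr) * sum_i tau_hat(X_i)^2
       - (1/N_tr + 1/N_est) * sum_leaves [ S2_treated/p + S2_control/(1-p) ]
  ```

  with split points chosen on one half of each household-level subsample and
  leaf effects re-estimated on the other ("honesty").  Predictions use the
  adaptive locally weighted estimator
  `tau_hat(x) = sum_i a_i(x) w_i (Y_i - m_i)(Z_i - e_i) / sum_i a_i(x) w_i (Z_i - e_i)^2`,
  where `a_i(x)` are forest kernel weights.

- **Overall and subgroup effects** (ATE / GATEs) by averaging per-person
  AIPW scores
  `gamma_i = m(X_i,1) - m(X_i,0) + (Y_i - m(X_i,Z_i))(Z_i - e_i) / (e_i (1 - e_i))`
  with survey weights and household-cluster-robust standard errors; subgroup
  estimates over any partition recombine exactly to the overall estimate.

- **Complier effects** (LATE) by the ratio of the outcome and first-stage
  score averages (delta-method clustered SEs), and individualized complier
  effects by an instrumental forest.

- **Heterogeneity diagnostics**: the best-linear-predictor calibration test
  (plug-in and cross-fitted variants), targeting operator characteristic
  (TOC) curves and the rank-weighted average treatment effect (RATE).

- **The uptake funnel**: three causal forests with outcomes
  applied / approved / enrolled decompose where in the funnel heterogeneity
  arises.

A synthetic-data module (`dgp_config()` / `generate_sample()`) generates
household-randomized lottery worlds with known ground truth — covariate
prevalences modelled on the in-person lottery sample, covariate-dependent
application and approval, ~2% control crossover, survey weights, and
configurable effect heterogeneity — so every stage is testable without the
restricted-use data.

## Worked example

```r
library(hforest)

cfg <- dgp_config(n_households = 3200)       # lottery world, known truth
g   <- generate_sample(cfg, seed = 1)

fit <- fit_causal_forest(g$sample, "mcs", params = forest_params(n_trees = 500),
                         seed = 1)
print(fit)
#> Honest causal forest: 500 trees, n = 3961 (0 dropped), p = 19, 3200 households
#>   outcome: y_mcs, treatment: Z
#>   out-of-bag CATE: mean 0.6442, sd 0.0814

ate <- average_effect(aipw_scores(fit))
print(ate)
#> y_mcs [overall]: 0.66 (95% CI 0.0194 to 1.301), SE 0.3268
#>   n = 3961 persons in 3200 households
```

The default world gives the mental-component score a constant true effect of
0.5; the doubly robust estimate 0.66 (SE 0.33) covers it.  Subgroup
effects, the calibration test, and the three-stage uptake decomposition:

```r
masks <- make_subgroups(fit$sample)          # overall + 21 prespecified subgroups
gate_table(fit)                              # tidy ATE/GATE table
calibration_test(fit)                        # plug-in omnibus heterogeneity test
calibration_test_crossfit(g$sample, "mcs")   # cross-fitted, nominal type-I error
uptake_decomposition(g$sample)               # applied -> approved -> enrolled
```

`run_analysis()` orchestrates the full pipeline (tuning, two-stage covariate
selection, per-outcome ITT and optional IV passes, balance table) and
`write_results()` emits tidy CSVs plus a JSON manifest.

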