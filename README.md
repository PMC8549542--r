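# hedonometer

Computational modelling of momentary happiness during a reinforcement
learning task with both extrinsic (points) and intrinsic
(skilled-performance) rewards — a "computational hedonometer" for
researchers in computational psychiatry and affective science who want
to quantify how much each reward source contributes to a person's
affective state.

Momentary happiness reported at a probe after trial *t* is modelled as
an exponentially discounted sum of recent task events:

    H(t) = [w0] + w_r * Σ_j γ^(t−j) R_j + w_p * Σ_j γ^(t−j) P_j + ε,
    ε ~ N(0, σ)

with `R_j` the z-scored points outcome of the chosen option, `P_j` the
z-scored success indicator of the barrier-navigation component (1 = no
collision), and forgetting factor `γ ∈ [0, 1]`. Four variants (reward
only, performance only, both with shared γ, both with separate γs) are
fit per subject by bounded least squares and compared by summed BIC.
The package also provides:

* a full task simulator (two Gaussian reward options, 50/25 ± 10
  points, reversals every 19–23 trials, half forced choices, happiness
  probes every 2–3 trials) so every analysis is testable without data
  collection;
* a PEST adaptive staircase that holds barrier-navigation success near
  70% across simulated performers;
* parameter- and model-recovery pipelines on synthetic cohorts;
* behavioural statistics: condition splits with Wilcoxon signed-rank
  tests, Spearman covariate correlations, split-half parameter
  reliability.

## Worked example

```r
library(hedonometer)

# one synthetic subject and a model fit
sess <- simulate_subject(seed = 42)
fit <- fit_happiness(sess$trials, sess$ratings)
fit
#> Happiness model fit: reward_performance (zscored ratings)
#>      w_reward w_performance         gamma         sigma
#>         0.245         0.047         0.650         0.772
#> n = 50 ratings, RSS = 29.829, r^2 = 0.135, BIC = -14.091
```

A single noisy subject gives noisy estimates; the cohort level is where
the model's structure shows. `simulate_cohort()` draws 33 agents whose
true parameters vary around the group means, and
`compare_happiness_models()` fits all four variants to every agent:

```r
co  <- simulate_cohort(cohort_spec(n_agents = 33, seed = 1))
compare_happiness_models(lapply(co$sessions, function(s) s))
#> Model comparison (BIC summed across 33 subjects)
#>                        model k mean_r2  bic delta_bic
#>                       reward 2    0.29 -271       112
#>                  performance 2    0.10  193       576
#>           reward_performance 3    0.38 -383         0
#>  reward_performance_sepgamma 4    0.41 -315        67
```

The shared-γ reward + performance model wins (ΔBIC = 0): the extra
separate-γ parameter raises raw fit quality (`mean_r2`) but not enough
to justify its complexity. Parameter recovery on the same cohort shows
the estimator tracks the truth with little bias:

```r
parameter_recovery(co)
#> Parameter recovery, reward_performance model, 33 agents
#>      parameter spearman_rho mean_true mean_estimated  bias
#>       w_reward         0.87      0.42           0.40 -0.02
#>  w_performance         0.82      0.19           0.19  0.00
#>          gamma         0.66      0.49           0.52  0.03
#>          sigma         0.81      0.81           0.80 -0.02
```

And the behavioural split shows the signature the model explains:
subjects are happier right after high-reward outcomes and after
collision-free navigation (z-scored rating units, group mean ± SEM):

```r
condition_split_test(co$sessions, "reward_level")
#> Condition split (reward_level, z-scored ratings, n = 33 subjects)
#>   high_reward     0.231 +/- 0.023 (SEM)
#>   low_reward     -0.375 +/- 0.036 (SEM)
#>   Wilcoxon signed-rank V = 554, z = 4.89, p = 1.02e-06
```

`run_experiment(run_config(...))` orchestrates the whole pipeline
(simulate → behavioural stats → fits → comparison → recovery) into an
output directory of CSV tables plus a JSON manifest.

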