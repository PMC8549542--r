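---
title: "Modelling momentary happiness from reward and performance history"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling momentary happiness from reward and performance history}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hedonometer)
```

## The model

People's momentary affective state during a task is well described as a
leaky accumulator of recent events. `hedonometer` implements this idea
for a reversal-learning task with two reward sources: explicit points
(extrinsic reward) and error-free skilled cursor navigation (intrinsic
reward). Happiness reported at a probe after trial $t$ is modelled as

$$
H(t) \;=\; [\,w_0\,] \;+\; w_r \sum_{j=1}^{t} \gamma^{\,t-j} R_j
\;+\; w_p \sum_{j=1}^{t} \gamma^{\,t-j} P_j \;+\; \epsilon,
\qquad \epsilon \sim N(0, \sigma),
$$

where $R_j$ is the z-scored points outcome of the chosen option on trial
$j$, $P_j$ is the z-scored success indicator of the navigation component
(1 = no barrier contacted, 0 = at least one collision), and the
forgetting factor $\gamma \in [0,1]$ discounts distal events: $\gamma =
0$ means only the most recent trial matters, while $\gamma \approx 0.5$
spreads influence over roughly the last four to five trials. Four
variants are compared: reward only, performance only, both terms with a
shared $\gamma$, and both terms with separate forgetting factors
(`happiness_model_family()`). Fits to raw ratings add a baseline mood
intercept $w_0$ (an affective set point on the rating line); fits to
z-scored ratings omit it, because standardized ratings and standardized
regressors are centred on zero.

### Parameters and units

| parameter | units | default generator value | meaning |
|---|---|---|---|
| `w_reward` | rating units per z-scored point | 0.39 | weight of extrinsic reward history |
| `w_performance` | rating units per z-scored success | 0.18 | weight of intrinsic (skill) reward history |
| `gamma` | dimensionless, $[0,1]$ | 0.48 | per-trial forgetting factor |
| `sigma` | rating units | 0.85 | Gaussian probe-noise SD |
| `w0` | raw rating units | 62 | baseline mood (raw-rating fits only) |

The z-scored-mode generator defaults are the published group-mean
estimates for this task; they make synthetic cohorts whose fit quality
(mean $r^2 \approx 0.26$–$0.30$) matches what the model achieves on real
raters. Raw-mode defaults place the baseline near the observed mean of
the 0–100 rating line with proportionally scaled weights and noise.

## The task simulator

`simulate_subject()` emulates the full session: two options with
Gaussian payoffs ($N(50, 10^2)$ high, $N(25, 10^2)$ low), a reversal of
the high option every 19–23 trials, half free / half forced choices
(forced options alternate high/low with a random phase), four barriers
navigated at a staircased cursor speed, and a happiness probe every 2–3
trials. The default session length is 120 trials in 2 blocks, yielding
about 48 probes — enough for stable four-parameter fits; the number of
trials per block is a package choice exposed in `task_config()`, not an
empirical fact.

The model itself makes no claim about how choices arise, so choices come
from deliberately standard plumbing: a delta-rule value learner with
softmax choice (`agent_spec()`, learning rate 0.3, inverse temperature
0.25 per point). These values give cohort free-choice accuracies in the
high 70s percent — learners that track reversals well above chance. The
happiness analysis conditions only on the realized choice/outcome
stream, so its validity does not depend on the choice model being right.

Rating generation adds $N(0,\sigma)$ noise to the model prediction at
each probe. Raw-mode ratings are clipped to the physical 0–100 line;
standardized-mode ratings are unclipped. A pre-task rating is emitted
with a `pre_task` flag and excluded from fitting by default, since its
status in model estimation is ambiguous for real sessions too.

### What the simulator does not emulate

Real raters drift, anchor, and settle in early in a session
(`trim_and_detrend()` exists for exactly that robustness check); real
choice sequences show autocorrelation, lapses and fatigue that the
delta-rule agent lacks; and real happiness has sources outside the task.
Passing recovery tests on this generator therefore demonstrates that the
*estimator* is sound under the model's own assumptions — it cannot prove
the model is complete for human data.

## The PEST staircase

Skilled-performance success must sit near a fixed rate across agents
(otherwise performance effects confound with skill differences), so
cursor speed is controlled by a PEST staircase (`init_staircase()`,
`pest_update()`): trial outcomes accumulate into a run; when successes
deviate from `target_p * trials` by more than a Wald limit, speed steps
toward the target (excess success speeds the cursor up, making the task
harder), and step sizes follow the classic heuristics — halve on
reversal, double from the third same-direction step, with the usual
exception after a reversal that follows a doubling. The PEST literature
fixes no constants; this implementation uses a Wald limit of 1 expected
success, an initial step of 10% of the starting speed clamped to
[1%, 50%], and a 60-trial calibration block before the task. The ~70%
fixed point is insensitive to these choices: 100 simulated logistic
performers held for 2,000 staircased trials succeed on 69–70% of trials.

## Fitting and model comparison

`fit_happiness()` minimizes the residual sum of squares between observed
and predicted ratings. At fixed $\gamma$ the weights enter linearly, so
they are profiled out by ordinary least squares and the bounded search
runs only over $\gamma$ (1-D, or 2-D for the separate-$\gamma$ model),
multi-started from 10 evenly spaced $\gamma$ values (a 2-D grid of
starts for the separate-$\gamma$ surface). Ties between restarts break
deterministically: lowest RSS, then lowest $\gamma$. The decayed sums
are evaluated by the recursion $S_t = \gamma S_{t-1} + x_t$; the test
suite checks this against an explicit double-loop evaluation at
`1e-12`, and checks the optimizer against a dense $\gamma$-grid with
closed-form weights.

Numerical choices: convergence tolerance `1e-8` on the RSS; weights
nominally bounded at $\pm 10$ in z-scored mode (the profiled solution is
checked and a warning raised if it escapes, which does not occur on
non-degenerate data); $\sigma$ is the maximum-likelihood residual SD
$\sqrt{\mathrm{RSS}/n}$, consistent with the Gaussian profile likelihood
and with $\sigma$ being excluded from the parameter count below. A
zero-variance regressor (for instance, an agent who never collides)
raises an error naming the degenerate column rather than returning a
silent `NA`. Noise-free data drive the RSS to numerical zero, where BIC
degenerates; `fit_happiness()` reports `-Inf` in that limit and
`compute_bic()` errors explicitly at RSS = 0.

Model comparison (`compare_happiness_models()`) sums
$\mathrm{BIC} = n\ln(\mathrm{RSS}/n) + k\ln n$ across subjects, with $k$
counting weights, forgetting factor(s) and, in raw mode, $w_0$ (so
$k = 2/2/3/4$ for the four variants). The constant $n(1+\ln 2\pi)$ is
shared by all models and dropped; only BIC differences are meaningful,
and all conclusions are drawn at the $\Delta$BIC level. Ratings are
z-scored within subject before comparison so that subjects with wider
rating scales do not dominate. Z-scoring here and for the regressors
uses the population-SD convention (divide by $n$) over the full session;
a within-block variant is used by `split_half_reliability()`.

## Recovery analyses

Individual-subject parameter estimates for the published task are not
available, so `cohort_spec()` samples agent parameters from normal
distributions matched to the published group statistics: mean $\pm$ SEM
with between-agent SD $= \mathrm{SEM}\sqrt{33}$, $\gamma$ truncated to
$[0,1]$ and $\sigma$ truncated positive. This preserves the location and
spread that recovery correlations depend on, but it is an approximation
to the real (non-Gaussian) parameter population, and two consequences
are visible in the acceptance checks:

* the rank-recovery correlation for `w_performance` measures about 0.83
  here versus the published 0.73 — with ~48 probes per agent the
  estimation SE of the performance weight is about 0.11, and with
  between-agent SD 0.17 the expected attenuation is
  $0.17/\sqrt{0.17^2 + 0.11^2} \approx 0.84$;
* per-agent best-BIC model identification is *not* diagonal-dominant for
  the two-term generative models: at the group-mean effect size the
  performance term's expected RSS improvement
  ($\approx n\,w_p^2\,\mathrm{var}(S_p)/\sigma^2 \approx 2.9$) is below
  the BIC penalty $\ln 48 \approx 3.9$, so BIC correctly prefers the
  single-term model for the median agent. The cohort-level summed-BIC
  ranking — the quantity the published comparison table actually
  reports — does reproduce: the shared-$\gamma$ reward + performance
  model wins and the separate-$\gamma$ variant is penalized below it.

Both facts are properties of the stated simulation conditions, left
visible rather than tuned away.

`parameter_recovery()` fits the generative model to every simulated
agent and reports per-parameter Spearman correlations and biases (the
noise SD enters as true $\sigma$ against estimated residual SD);
`model_recovery()` builds the generative-model $\times$ best-BIC-model
confusion matrix. With all parameter SDs at zero the truth carries no
rank signal, correlations are reported as `NA`, and only bias is
interpretable — the regime used for the unbiasedness checks.

## Behavioural statistics

`condition_split_test()` assigns each rating to the condition of the
immediately preceding trial — the only unambiguous trial-to-probe
mapping when probes follow every 2–3 trials; a window-averaging variant
(`window = "since_previous_probe"`) is available for sensitivity
analysis. The reward condition is defined by whether the *currently
high-mean* option was chosen, not by a points threshold. Group tests are
two-sided Wilcoxon signed-rank tests across subjects with no
multiplicity correction, and `correlate_covariate()` provides Spearman
correlations for parameter–covariate checks. Questionnaire instruments
are out of scope: covariates are generic numeric vectors.

## Problem sizes and determinism

Every stochastic component flows from explicit seeds: cohorts derive
per-agent seeds from the cohort seed, so any manifest regenerates
bit-identically, and `run_experiment()` writes a JSON manifest with the
global seed. The packaged checks use 33-agent cohorts (matching the
published sample size) for fit-quality and recovery-correlation
comparisons, 120–200 agents for bias estimation, 100 performers
$\times$ 2,000 trials for the staircase fixed point, and 20 seeded
8-agent cohorts for the model-recovery confusion matrix; these sizes are
package choices balancing Monte-Carlo error against convenience.

## Known limitations

* The choice model is plumbing, not psychology; nothing should be
  inferred from its parameters.
* The parameter population for recovery is a normal approximation to an
  unavailable empirical distribution (consequences quantified above).
* Expectation-based happiness terms (reward prediction errors,
  anticipation) are deliberately not implemented: the task design holds
  performance near a fixed rate and separates the two options' payoffs,
  which makes expectation effects poorly identified in this paradigm.
* Raw-rating mode treats the rating line as [0, 100] with a midpoint
  start; generated raw ratings are clipped at the ends, which slightly
  biases extreme-baseline simulations.
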