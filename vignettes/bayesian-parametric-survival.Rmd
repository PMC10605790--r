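---
title: "Bayesian parametric survival models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian parametric survival models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the model, the inference machinery, the updating
and evaluation procedures, and the design decisions behind `bpsurv` — the
things a user should know before trusting the numbers it produces.

## The model

For subject $i$ with covariates $x_i$, observed time $t_i > 0$ and event
indicator $\delta_i \in \{0, 1\}$ ($1$ = event observed, $0$ =
right-censored), the survival time follows either an Exponential or a
Weibull distribution in the *rate* parameterization:

$$S(t \mid \lambda, \kappa) = \exp\{-(\lambda t)^\kappa\},$$

with $\kappa \equiv 1$ for the Exponential case. Two readings make this
parameterization convenient: $1/\lambda$ is the time by which the event
probability reaches $1 - e^{-1} = 63.2\%$ regardless of the shape, and
$\kappa$ says whether the event rate rises ($\kappa > 1$), falls
($\kappa < 1$) or stays constant ($\kappa = 1$) — at $\kappa = 1$ every
Weibull quantity collapses exactly onto the Exponential one, which the
test suite asserts to $10^{-12}$. Note that many R functions
(`dweibull`, `flexsurv`) use the scale $\beta = 1/\lambda$; conversions
must invert the rate.

The rate (and optionally the shape) is predicted from covariates through
one of two positive-valued functions:

* **linear**: $\lambda = \exp(\theta_0 + \theta^\top x)$ — an intercept
  column is prepended internally, callers never supply it;
* **neural network**: tanh hidden layers
  $a^{l} = \tanh(W^l a^{l-1} + b^l)$ followed by an exponentiated linear
  output layer, one output per distribution parameter.

For the Weibull model the shape is, by default, a single shared
intercept, $\kappa = \exp(\theta_{\kappa 0})$ (`kappa_mode =
"intercept_only"`); the full covariate-dependent shape is available but
makes the likelihood surface noticeably harder and is rarely warranted at
clinical sample sizes.

**Likelihood.** Censored subjects contribute the log survival
$\log S(t_i)$ — the probability that the true time exceeds the observed
one. Event subjects contribute the log density, i.e. log hazard + log
survival:

$$\ell_i = \delta_i\bigl[\log\kappa + \kappa\log\lambda_i +
(\kappa - 1)\log t_i\bigr] - (\lambda_i t_i)^\kappa .$$

The density term for events is the standard censored-likelihood
construction; the package derives it from the stated distribution rather
than treating events and censorings asymmetrically.

**Priors.** Every coefficient, weight and bias receives an independent
$\mathrm{Normal}(0, \sigma)$ prior with $\sigma = $ `prior_sd` (default
1). On normalized covariates this is weakly informative and acts as the
model's only regularizer — which is why the tuning space for these models
is just `prior_sd` and the number of selected features.

## Posterior sampling

The package fits by dynamic Hamiltonian Monte Carlo with a No-U-Turn
termination rule — the doubling/slice-variable scheme with dual-averaging
step-size adaptation (target acceptance 0.9) and a diagonal mass matrix
estimated from a window in the middle of warmup. Gradients of the log
posterior are analytic for all variants (backpropagation for the network
predictor), which keeps a pure-R sampler fast enough for the problem
sizes the models are intended for (hundreds to a few thousand subjects,
tens of parameters). Defaults: 4 chains, 1000 warmup, 1000 kept draws —
conventional settings that pass split-$\hat R < 1.01$ comfortably on
identified models.

Convergence problems *warn* rather than fail: cross-validation and
partition-stream loops must run unattended, and the diagnostics
(split-$\hat R$, effective sample size, post-warmup divergence count)
travel with the fitted object so they can be inspected afterwards. Fixing
`seed` makes fits bit-for-bit reproducible; chain $c$ uses `seed + c - 1`.

The network predictor deserves a caveat: its weights are not individually
identified (hidden-unit permutations and sign flips leave the likelihood
unchanged), so per-weight $\hat R$ is routinely large even when the
*predictions* — the identified quantities — are stable. Recovery for this
variant is therefore assessed on predicted median survival, not on
weights, and the sampler cap `max_treedepth` is worth lowering (6–8) to
keep tree growth in the non-identified directions affordable.

## Prediction

`predict_survival()` evaluates $S(t)$ on a time grid under every retained
posterior draw and reports, per subject and time point, the mean and SD
of the survival probability, with the default uncertainty band mean ± 1
SD clipped to $[0, 1]$; central quantile bands are available as an
option. At $t = 0$ the curve is exactly 1 with zero SD. Median survival
per draw is closed-form, $\log(2)^{1/\kappa}/\lambda$.

For ranking-based evaluation the risk score of a fitted model is the
negative posterior-mean median survival — for the Exponential model this
ranks subjects identically to the rate $\lambda$, and the C-index is
invariant to any strictly monotone rescoring. External models plug into
the same evaluation through a plain `function(X) -> scores` adapter.

## Updating by Bayes' rule

`posterior_to_priors()` summarizes each parameter's marginal posterior as
$\mathrm{Normal}(\text{mean}, \text{widen} \times \text{SD})$ and
`bps_update()` refits on the new data alone with those priors. This is a
deliberate approximation: posterior correlations are discarded, because
the hand-off artifact is meant to be a small, human-readable summary that
can cross institutional boundaries where subject-level data cannot. Two
consequences are documented rather than hidden:

* repeated updating on the same information concentrates the posterior
  roughly like pooling the data (the test suite checks the
  $1/\sqrt{2}$-ish SD shrinkage when the same cohort is seen twice);
* where the marginal-Normal approximation loses information, the overlap
  index (below) between full-retraining and updating posteriors drops —
  that is the intended diagnostic, mirroring how re-training risk should
  be monitored before deployment.

`widen > 1` deflates the carried-over information for the case where the
old model was trained on a very large cohort and would otherwise swamp
the new data.

The partition-stream protocol (`run_updating_experiment()`) emulates data
arriving over time: at step $k$ the test set is partition $k + 1$; update
mode trains on partition $k$ with priors from step $k-1$, full-retrain
mode trains on partitions $1..k$ from scratch. Update mode never touches
rows from earlier partitions — the privacy contract is structural (the
function receives only the newest partition and the previous model's
summaries).

## Evaluation statistics

* **C-index** (Harrell): over comparable pairs — $t_i < t_j$ with
  $\delta_i = 1$ — the fraction where the earlier failure has the higher
  risk; risk ties count $1/2$; pairs with tied event times are treated as
  non-comparable (Harrell's convention; with no comparable pairs the
  index is 0.5 with a warning). An $O(n^2)$ brute-force pair count and
  `survival::concordance` serve as independent cross-checks in the tests.
* **Overfitting gap**: training-set minus test-set C-index.
* **HDI**: narrowest interval holding the requested mass, by a sliding
  window over sorted draws. ("Highest-density interval" is the standard
  reading; for multimodal posteriors a single interval is an
  approximation.)
* **ROPE equivalence**: the difference's HDI (98.33% by default,
  $1 - 0.05/3$ after Bonferroni for 3 comparisons) against a region of
  practical equivalence (±0.01 C-index by default) — *accepted* only if
  the whole interval is inside, *rejected* only if it is entirely
  outside, otherwise *undecided*; `pct_in_rope` is the fraction of the
  interval's length inside.
* **Overlap index (OVI)**: $\int \min(f_a, f_b)$ with each density
  estimated by Gaussian KDE. Bandwidths use Silverman's rule-of-thumb on
  each sample separately, integrated on a shared 512-point grid spanning
  the pooled range padded by three bandwidths. Any OVI is reproducible
  only up to the bandwidth convention, so the convention is fixed and
  documented; the suite checks the closed-form Gaussian benchmark
  $\mathrm{OVI}(N(0,1), N(1,1)) = 2\Phi(-1/2) \approx 0.617$ to ±0.01.
* **Superiority sample size**: exact noncentral-$t$ power inversion via
  `stats::power.t.test`, rounded up. With $\delta = 0.02$, $\mathrm{SD} =
  0.025$, $\alpha = 0.05/15$ (six models, 15 pairwise comparisons),
  power 0.8: 47 per group.

## The ML pipeline

Experiment-style evaluation composes: an 80/20 seeded train/test split;
z-scoring of continuous columns by *training* statistics only (binary and
one-hot columns pass through); feature ranking by mutual information with
the binarized outcome "time above the median"; and cross-validated
selection of `prior_sd` (log-uniform over $[0.1, 10]$), $k$-best features
and, for the network, the number of hidden layers.

Three choices here were genuinely open and are fixed as follows. The
outcome is binarized at the *observed-time* median — the simplest
reading; a Kaplan–Meier-style median is available via `median_type =
"km"` since the observed median is biased low under heavy censoring. MI
for continuous features uses the Ross nearest-neighbour estimator with 3
neighbours and a seeded $10^{-10}$-scale jitter (discrete features use
plug-in contingency MI); the estimator matters less than its consistency,
and the seed makes rankings reproducible. The search strategy is seeded
random search; with a 2–3 dimensional, mostly-flat objective, sequential
model-based search adds machinery without changing which configuration
family wins, and the `scorer` injection point lets tests (or users)
replace the search wholesale. Fold assignment is event-stratified so no
fold is left without events.

Pipeline hygiene is structural: normalizers and feature rankings are
built from the training fold object only, so mutating held-out rows
cannot change them (asserted in the tests).

## The synthetic-data generator

`simulate_survival()` draws standard-normal continuous and
Bernoulli(0.5) binary covariates, sets $\lambda_i = \exp(x_i^\top
\theta)$, and inverts the survival function ($T = (-\log U)^{1/\kappa} /
\lambda$). Censoring is either *administrative* — a fixed cutoff at the
$(1 - \text{target})$ quantile of the realized event times, the study-end
mechanism — or *uniform* on $(0, c)$ with $c$ solved numerically so the
expected censored fraction hits the target. The generator emulates the
data-generating assumptions of the model family itself: linear
log-rates, proportional effects, independent censoring. It deliberately
does *not* emulate covariate correlation, non-linear or time-varying
effects, informative censoring, or measurement error — so passing
recovery tests shows correctness of the inference machinery, not that
the model fits any particular real cohort.

Default study conditions used across the tests and the acceptance
script: cohorts of 500 (600 for the updating stream, split into 6
partitions), ~30% administrative censoring, coefficients of magnitude
0.4–0.8 on standardized covariates, Weibull shape 1.5 — moderate,
clinically plausible effect sizes and censoring.

## Numerical choices and degenerate inputs

* Positivity of $\lambda, \kappa$ is enforced by exponentiation; the
  sampler works on the unconstrained scale, so no Jacobian corrections
  arise.
* Non-finite likelihood evaluations (overflow of $(\lambda t)^\kappa$ at
  extreme proposals) return $-\infty$ and are rejected as divergences
  rather than crashing; the post-warmup divergence count is reported.
* Times must be strictly positive; the generator bumps
  numerically-zero times to half the smallest positive value, loudly.
* All-censored data fit (the posterior tracks the prior, with a
  warning); zero-variance columns normalize with scale 1, with a
  warning; a degenerate (zero-SD) posterior refuses to become a prior.
* Model files are versioned JSON; a summaries-only file supports
  updating exactly and prediction approximately (independent Normal
  draws, with a warning).

## Problem sizes in the checks

The test suite and acceptance script run entirely on simulated data at
desk scale: recovery uses 20 replicates of $n = 500$ with 2 chains ×
250/250 iterations (the coverage target, ≥ 80% of 94% HDIs, is robust to
this draw count); the updating equivalence uses 15 replicates of the
6-partition stream; the network variant uses $n = 120$ with a 2-unit
hidden layer. These sizes were chosen so the entire evidence base
rebuilds from scratch in minutes while keeping every statistical
conclusion comfortably away from its threshold.

## Known limitations

* Only right censoring; no left/interval censoring, competing risks,
  time-varying covariates, or frailty terms.
* Only Exponential and Weibull families (no Gompertz/log-normal/
  log-logistic).
* Updating transports marginal Normals, not the joint posterior; with
  strongly correlated parameters the updated model can differ from full
  retraining even when predictive performance does not (watch the OVI).
* The pure-R sampler is adequate for the intended problem sizes but not
  for large networks or $n \gg 10^4$; the network predictor's
  non-identifiability makes its per-weight diagnostics pessimistic by
  construction.
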