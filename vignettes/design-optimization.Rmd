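---
title: "Simulation-based optimization of classical conditioning experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulation-based optimization of classical conditioning experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condesign)
```

## The design problem

A classical (Pavlovian) conditioning experiment presents, on each trial, one
conditioned stimulus (CS) followed with some probability by an outcome (US),
and records a conditioned response (CR). Because learning in these paradigms
is driven by the statistical contingencies between cues and outcomes, the
experiment can be formalized as a *trial-generating Markov chain*: the cue
probabilities `P(CS)` and the conditional outcome probabilities `P(US|CS)`
are the chain's transition probabilities, and they are the design variables
a planner can tune. `condesign` supports two low-dimensional
parameterizations of that chain:

* **stage-wise** — the experiment is a sequence of blocks, each with
  constant transition probabilities. Blocking, backward blocking, reversal
  learning and similar classical paradigms are special cases
  (`stagewise_design()`, `build_reference_design()`).
* **periodic** — every transition probability follows a square wave with
  levels $P_1$ and $P_2$ and a shared half-period $T$ (a fraction of the
  total trial count), which expresses frequently changing environments with
  three variables per probability (`periodic_design()`).

Whether a proposed design is *good* depends on what the experimenter plans
to do with the data. The package scores a design by the **Monte-Carlo
expected utility** of the planned analysis: sample a ground-truth model and
parameters from a prior, simulate a full dataset under the design, run the
planned analysis on the simulated data, and score the outcome — negative
absolute estimation error for parameter-estimation goals, the 0/1
correct-model indicator for model-selection goals
(`expected_design_utility()`). Averaging over simulated experiments gives
the expected design utility, and a Gaussian-process Bayesian optimizer tunes
the design variables to maximize it (`optimize_design()`).

## The candidate models

Three families of trial-level associative learning models are implemented,
all emitting a mean response to the presented cues plus homoscedastic
Gaussian observation noise $\sigma_{obs}$ (the US is coded 0/1 and the
asymptote $\lambda$ is fixed at 1; its scale is absorbed by the weights):

* **Rescorla-Wagner (`rw`)** — delta-rule learning,
  $\delta_t = \lambda r_t - x_t^\top w_t$, $w_{t+1} = w_t + \alpha\,\delta_t x_t$,
  with response $x_t^\top w_t$. The learning rate $\alpha$ is the parameter
  of interest in the estimation scenario.
* **Kalman Rescorla-Wagner (`krw`)** — a Bayesian extension holding a full
  Gaussian belief $N(w_t, \Sigma_t)$ over the weights, with per-trial
  diffusion $\Sigma \mathrel{+}= q I$ and a conjugate Kalman update
  (parameters: prior variance `w0_var`, drift `q_diffusion`, outcome noise
  `r_noise_var`). The off-diagonal covariance acquired on compound trials
  lets the model revalue absent cues — the signature of backward blocking.
* **Hybrid Rescorla-Wagner/Pearce-Hall (`rwph_v`, `rwph_alpha`,
  `rwph_valpha`)** — weight learning modulated by per-cue dynamic learning
  rates ("associabilities") that track $|\delta|$:
  $V \mathrel{+}= \kappa\,\alpha_i\,\delta$ and
  $\alpha_i \leftarrow \eta |\delta| + (1-\eta)\alpha_i$ for presented cues.
  The three variants emit the weights, the associabilities, or their
  $\omega$-mixture as the response. With $\eta = 0$ the family collapses to
  Rescorla-Wagner with rate $\kappa\alpha_0$; the models are nested, which
  the test suite exploits as an exact likelihood identity.

The recursions exist twice: single-trial reference steps in R
(`rw_step()`, `krw_step()`, `rwph_step()`) and vectorised C++ filters used
by simulation and likelihood evaluation. The tests require the two routes
to agree exactly, trial by trial. The response is always emitted from the
*pre-outcome* prediction of the current trial — the subject responds to the
CS before the US arrives; this timing is a modelling choice of this package.

## Analysis procedure and its numerics

The planned analysis is maximum-likelihood estimation under uniform box
priors (equivalently, MAP) with BIC model selection (`fit_mle()`, `bic()`,
`select_model()`), using $n$ = number of trials as the BIC sample size and
counting $\sigma_{obs}$ among the fitted parameters. Numerical choices that
matter:

* **Profiled noise.** For fixed dynamics parameters the Gaussian MLE of
  $\sigma_{obs}$ is the root-mean-squared residual (clamped to
  `[0.01, 1]`), so the search runs only over the dynamics parameters. This
  is exact, not an approximation, and roughly halves the search dimension.
* **Screen-then-polish multistart.** The hybrid models' likelihood surfaces
  are multimodal, and their nested sub-models live on *boundary faces* of
  the parameter box ($\eta = 0$ freezes the associabilities; $\omega = 0$ or
  $1$ collapses the response mixture). `fit_mle()` therefore ranks a cloud
  of uniform candidate points (covering the closed box) by the profiled
  likelihood, starts bounded L-BFGS-B searches from the best `n_starts`
  (default 5), and adds one extra start per nested face — the best
  face-projected candidate. This guarantees in practice that a richer model
  never undercuts a model it nests, which BIC comparisons rely on.
* **Transforms, not penalties.** Variance-type KRW parameters are searched
  on $\log_{10}$ scale within `[1e-4, 10]`; box constraints are enforced by
  L-BFGS-B directly. Finite-difference steps are `1e-6` and convergence
  tolerances tight (`factr 1e5`, `pgtol 1e-8`) because BIC differences of
  order $10^{-4}$ can flip nested-model comparisons.
* **Ties.** Exact BIC ties go to the model with fewer parameters, then to
  declaration order. Restart seeds derive from the model identity, so
  selection does not depend on the order models are listed.

Analyses that fail inside a utility evaluation are scored at the worst case
(0 for selection, a configurable penalty for estimation) rather than
dropped, which would bias expected utility upward.

## The optimizer

Expected-utility evaluations are Monte-Carlo noisy and relatively
expensive, so the optimizer is Bayesian optimization with a Gaussian-process
surrogate: anisotropic Matérn-5/2 kernel with a fitted noise term,
hyperparameters set by maximizing the marginal likelihood from several
starts, and an expected-improvement acquisition (exploration offset `xi` on
the standardized output scale) maximized by dense candidate search plus
local polish. When the acquisition degenerates — every point promises no
improvement, as happens once a noiseless objective is essentially solved —
the proposal falls back to maximizing the posterior mean rather than to
random exploration.

Two conventions deserve note. The trace's `incumbent` column is the running
maximum of *observed* utilities (monotone by construction), but the design
returned at the end is the evaluated point with the highest GP *posterior
mean*: raw argmax over noisy observations is optimistically biased, the
posterior mean is not. And the simplex constraints on cue probabilities are
handled inside `from_vector()` by a stick-breaking transform, so the
surrogate always sees the plain unit box and every proposal decodes to a
valid design; the residual probability goes to the last stimulus, and the
half-period decodes with `ceiling(T * n_trials)` trials per block so that
`T = 1` is a constant schedule and no block is ever empty.

Per-evaluation seeds derive deterministically from the master seed and the
iteration number: runs are exactly reproducible, but evaluations do not
share random numbers (no common-random-numbers coupling across iterations).

## The shipped scenarios and what the generator assumes

Three end-to-end scenario configurations are installed under
`inst/extdata/` and loaded with `load_scenario_config()`:

1. **Learning-rate estimation** — single cue, periodic reinforcement;
   reference design: acquisition at 50% reinforcement then extinction, one
   mid-experiment switch; evaluation priors fix $\alpha$ at 0.1, 0.2, 0.3;
   design space $P_1, P_2, T$ (3 variables).
2. **RW vs KRW selection** — reference design: backward blocking (AB+ then
   A+ then a non-reinforced test of A and B); optimized space: two stages,
   three presentable stimuli, 10 non-redundant variables.
3. **RW vs RWPH-variant selection** — reference design: reversal learning;
   optimized space: two stages, two cues, 6 non-redundant variables.

Several numeric settings of the underlying studies are not published in
sources available to this package and are therefore *package defaults*,
declared in the YAML configs with `assumed: true` and a provenance note:
the per-stage trial counts (160 = 80+80; 20/20/10; 60+60 at 0.7 partial
reinforcement), the observation noise $\sigma_{obs} = 0.1$, and the
point-prior parameter values of the KRW and hybrid models. The vague design
priors are uniform for bounded parameters and weakly-informative
half-normals for variances. Test-stage trials contribute to the fitted
likelihood like any other trial.

**What the generator does and does not emulate.** Simulated data share the
trial structure, the generative models and the noise model of the planned
analysis — simulation and analysis are *well specified* relative to each
other. Real conditioning data are not so kind: responses are non-Gaussian
and often bounded at zero, noise is heteroscedastic, subjects drift in
attention, and none of the candidate models is the true data-generating
process. Passing tests therefore demonstrate the correctness and internal
consistency of the machinery, not that an optimized design will improve a
particular empirical study.

**A known ceiling effect.** Under the shipped defaults the *reference*
designs already discriminate their model spaces almost perfectly: with
$\sigma_{obs} = 0.1$, the five non-reinforced test trials of the
backward-blocking design carry a revaluation signal of roughly half a
response unit, an order of magnitude above the noise, so the BIC penalty
($2\ln 50 \approx 7.8$) is easily overcome and selection accuracy saturates
near 100%. The literature regime in which such reference designs sit near
60% accuracy corresponds to substantially noisier observations (roughly
$\sigma_{obs} \gtrsim 0.4$ at these trial counts). Design optimization then
has little headroom under the defaults; the improvement the method is built
to deliver becomes visible exactly when the reference design is *not*
already at ceiling. Users studying that regime should raise `sigma_obs` in
their scenario config — the package deliberately keeps the shipped value
fixed rather than calibrating it against published accuracy figures.

## Problem sizes

The test suite and the acceptance script run everything at desk scale, as a
package choice: reference evaluations use 512 (scenario 2), 256
(scenario 3) and 3 × 48–64 (scenario 1) simulations; optimizations run 20
Bayesian-optimization iterations with 8–16 simulated datasets per candidate
model per evaluation, followed by a fresh 96–256-simulation re-evaluation
of the returned design. Full-scale studies (hundreds of iterations, 32
datasets per model per evaluation, 256 evaluations per combination) use the
same code paths with larger option values, e.g.

```{r, eval = FALSE}
cfg <- load_scenario_config(2)
run_scenario(cfg, "optimize", seed = 1, out_dir = "results/s2",
             design_prior = "vague")       # 300 iterations, 32 sims/model
```

## A worked example

```{r}
cfg <- load_scenario_config(2)
cfg$reference_design

eu <- expected_design_utility(
  cfg$reference_design, cfg$evaluation_priors$all, analysis = "select",
  model_space = cfg$model_space, n_sims = 16, seed = 1)
eu
confusion_matrix(eu$truth_models[!is.na(eu$selected)],
                 eu$selected[!is.na(eu$selected)], cfg$model_space)$matrix
```

## Limitations

Beyond the ceiling effect above: only trial-level (not continuous-time)
models, so presentation timings cannot be optimized; single-subject
datasets only (no group or hierarchical structure); MLE/BIC as the sole
analysis family (no fully Bayesian posteriors or marginal likelihoods); no
adaptive, within-experiment design updating; and elemental cue
representations only (a compound activates its members' weights, with no
configural units).
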