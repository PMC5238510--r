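---
title: "Models and methods behind revlearn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind revlearn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The task and its data model

`revlearn` analyzes feature-based reversal learning: on every trial two
peripheral stimuli carry complementary values on three feature dimensions
— location (left/right), motion (up/down) and color (1/2) — and only
color predicts reward. The color–reward map is constant within a block of
30–50 trials and flips, un-cued, between blocks. A block advances early
once the running average of rewarded choices over the last 12 completed
trials reaches 0.90 (evaluated from trial 30 on), otherwise at the
50-trial cap. The six elementary feature values (L, R, up, down, color1,
color2) are the units over which all models operate; each stimulus is one
triple, the other stimulus the complementary triple.

The simulator (`generate_session()`, `simulate_condition()`) implements
exactly this world. Design choices worth knowing:

* Color-to-side and motion-to-side assignments are randomized
  independently with probability 0.5 each trial, so location and motion
  are pure distractor dimensions.
* The environment rewards a correct choice deterministically. The
  Bayesian models' assumed reward reliability `p_r = 0.99` is a property
  of the *models*, not of the task: it slows Bayesian integration to
  behaviorally plausible speeds and is kept fixed, never fit.
* Incomplete trials (fixation breaks, premature responses) exist only
  through an optional lapse rate, default 0, because every learning model
  conditions on completed choices. Lapse trials are excluded from the
  block-advance window.
* The first block's rewarded color is drawn from the session RNG; the
  rewarded color then alternates deterministically.
* Blocks are tagged with their exit route (`criterion` vs `cap`), since a
  block can end unlearned at the cap.

# The eight learning models

All models start a session with feature values `V_i = 0.5` and/or a
uniform posterior over the six candidate targets, score the observed
choice *before* updating, and carry values across the un-cued reversals
within a session (an agent cannot know a reversal happened); the belief
state is likewise reset only at session start.

1. **FV** — delta rule on the chosen triple, `V_i += eta (R - V_i)`;
   softmax over summed triple values with inverse noise `beta`.
2. **FV+Decay** — FV plus divisive decay of the unchosen triple,
   `V_i <- V_i / omega`, `omega >= 1` (identity at 1). The algebraic form
   of the decay was not recoverable from the source text; divisive decay
   is consistent with fitted values slightly above 1 meaning mild decay,
   and is isolated behind `decay_update()` so it can be swapped.
3. **FV+2Eta** — separate learning rates after rewarded (`eta1`) and
   unrewarded (`eta0`) outcomes.
4. **BI** — pure Bayesian integration: posterior over the six candidate
   targets updated by the outcome likelihood (`p_r` for candidates inside
   the chosen stimulus, `p_n = 1 - p_r` outside), stimulus valued by its
   posterior-predictive reward probability; one free parameter (`beta`).
5. **FW** — hybrid: the Bayesian posterior sets attention weights over
   dimensions, `w_d \propto g_d^alpha` with `g_d` the posterior mass of
   dimension `d`; the stimulus value is the weighted sum of its feature
   values; learning uses an *object-level* prediction error
   `R - V_stim(chosen)` applied to all chosen feature values.
6. **FW+ChoiceHistory** — FW plus color perseveration: a provisional
   softmax choice that repeats the previous color is accepted; otherwise
   it is accepted with probability `gamma`, else switched. The exact
   functional form in the source was not legible; a single free
   acceptance probability `gamma in [0, 1]` is the package's choice.
7. **FW+2Eta** — FW with outcome-dependent learning rates.
8. **FW+Decay** — FW plus divisive decay of the unchosen triple; the
   best-fitting model for this task in practice.

Free-parameter counts: 2, 3, 3, 1, 3, 4, 4, 4.

A consequence of the object-level prediction error deserves emphasis:
**FW with uniform weights does *not* reduce to FV.** The summed update
over the chosen triple is identical, but individual feature values
diverge (FV moves each `V_i` by its own error, FW moves all three by the
common object error), and future stimuli recombine features, so the
likelihood paths differ. The reductions that *are* exact — and are
verified to machine precision in the tests — are `eta1 = eta0` → FV and
`gamma = 1` → FW.

Numerical choices: softmax uses max-subtraction; a per-trial likelihood
floor of `1e-12` keeps the NLL finite; trials without a completed choice
contribute zero likelihood and no update. The likelihood is implemented
twice — an exported, readable R path (`trial_loglik()`,
`session_loglik_r()`) and a compiled path (`session_nll()`) used by the
optimizer — with a property test requiring agreement below `1e-10` on
all eight models.

# Fitting, cross-validation, comparison

`fit_model()` minimizes the NLL with a two-stage multi-start scheme
mirroring a simplex-then-quasi-Newton tradition: 5 random starts uniform
inside the bounds, each given a Nelder–Mead warm-up capped at 20
iterations and an `L-BFGS-B` refinement. Bounds — `eta, eta0, eta1 in
[0, 2]` (the delta rule is unstable past 2), `beta in [0, 20]`, `omega in
[1, 3]`, `alpha in [0, 5]`, `gamma in [0, 1]` — contain all published
estimates for this task with wide margins. One-parameter models use
Brent's method.

`cross_validate()` splits at the *block* level (blocks are the
exchangeable unit of reversal learning), 80/20, 100 replicates by
default: fit on the training blocks, evaluate the held-out blocks'
log-likelihood at the training optimum. Within a subset, state still
resets only at session boundaries; omitted blocks are skipped in the
sequence. AIC (`2k + 2 NLL`) is computed on the full-data fit.
`param_correlations()` gives the Pearson structure of the per-replicate
training optima; `model_behavior_ssd()` compares trial-since-reversal
choice-probability curves between model and data.

# The ideal-observer learning curve

Within each block, the trial-wise probability of a rewarded choice is
estimated with the state-space framework: a latent Gaussian random walk
`x_t = x_{t-1} + e_t`, `e_t ~ N(0, sigma_e^2)`, observed through a
Bernoulli outcome with `p_t = logistic(logit(chance) + x_t)`. The
*learning trial* is the first trial from which the lower confidence bound
(level 0.95 by default; configurable) exceeds chance for every remaining
trial of the block.

Two estimation choices differ from the textbook recipe, for cause:

* **Exact grid inference instead of the Gaussian-approximation
  filter/smoother.** The classical approximate filter sets the
  observation information to `p(1-p)`, which vanishes in long runs of
  correct trials; the smoothed variance then inflates without bound and
  detection can be *lost* by appending further correct trials — the
  opposite of what evidence accumulation demands. The package therefore
  discretizes the state on a 161-point grid over ±8 logits and runs the
  exact forward filter / backward smoother of the discretized model (in
  C++), with EM for `sigma_e^2`. EM on this exact likelihood is provably
  monotone, which the tests assert literally. The Gaussian-approximation
  path is retained internally and agrees with the grid on non-saturated
  sequences.
* **The boundary state is marginalized under a fixed `N(0, 1)` prior on
  the logit scale, not estimated as an EM point parameter.** Treating it
  as a parameter lets a flat chance-level block masquerade as a precisely
  known above-chance level (the curve inherits no uncertainty from the
  boundary), which produced ~18% false detections on chance-only data;
  with the prior, false detections run ~3% at the 95% criterion,
  consistent with the nominal level. Variance 1 on the logit scale is
  weakly informative around chance (roughly ±20 percentage points at one
  SD) and is not tuned.

EM stops at a relative log-likelihood change below `1e-6` or 500
iterations. Detection calibration measured by simulation: ≤5% false
detections on 1000 chance-only blocks; on step sequences (15 trials at
0.5, then 15 at 0.95) the median detected learning trial falls within ±3
trials of the step.

# Resampling statistics

`trialwise_permutation_test()` contrasts two conditions' per-trial median
probability-of-rewarded-choice across blocks (trials 1–30 since
reversal). The null reassigns block labels `n_perm` times; all per-trial
null differences are pooled into one distribution and its 95% order
statistic is the single threshold applied to every trial.

**Calibration caveat (an honestly failing criterion).** A single pooled
per-value threshold controls the *familywise* error rate at 5% only when
the 30 per-trial statistics are (nearly) perfectly dependent: for
independent statistics the chance that at least one of 30 exceeds a 95%
per-value quantile approaches 79%. Real per-block learning curves are
heterogeneous in learning trial and asymptote, so the 30 medians carry
perhaps a handful of effective degrees of freedom; measured familywise
false-positive rates are ~15–40% both on synthetic heterogeneous curves
and on the package's own simulator + state-space pipeline under random
label assignment (and higher with fewer blocks, where medians are
noisier). The acceptance suite implements the ≤5% calibration
check faithfully and it fails; the power companion (a +0.3 shift confined
to trials 8–10, 150 blocks per condition, flagged in ≥80% of runs) passes
with near-certainty. Users should read flagged trials as descriptive
unless the dependence assumption is defensible for their data.

`consistency_randomization()` asks whether one condition learns earlier
*consistently across a session*: median learning trials over 15 sliding
sets of four block positions (8 aligned to session start, 7 to session
end), statistic = proportion of positions earlier under the putatively
faster condition (ties conservatively count as not earlier), null built
by shuffling session labels, `p = 1 - rank` of the observed statistic.
Blocks without a detected learning trial are excluded throughout, since
learning-trial statistics are defined only for blocks that showed
learning.

# What the synthetic data does and does not establish

The generator reproduces the statistical structure the analyses assume:
block lengths and the 90%-of-12 advance rule, 1/3–1/3–1/3 dimming
conditions, complementary feature triples, choices from any of the eight
models at stated parameter values. It does not emulate reaction times,
saccade kinematics, motivational drift across a session, or
dose-dependent pharmacology. A green parameter-recovery test therefore
establishes that the fitting machinery is consistent (simulate → refit
returns the generative values within sampling error at the study's block
counts) — not that any particular parameter value describes a real
subject. Conversely, data-bound quantities from the original study (its
AIC of 3023.0, its median learning trials of 10 vs 12) are properties of
undeposited single-subject data and are deliberately not reproduction
targets.

# Known limitations

* The decay and choice-history equations are reconstructions behind
  strategy interfaces (`decay_update()`, `choice_history_filter()`); a
  different published form can be swapped without touching the fitter.
* The grid smoother's state range (±8 logits) saturates below
  probabilities of ~3e-4; blocks needing estimates outside that range are
  not meaningful in a 50-trial design.
* Cross-validated test log-likelihoods are computed at the training
  optimum only; no hierarchical pooling across conditions or subjects.
* The pooled-null permutation threshold is anti-conservative as a
  familywise controller (above); the sliding-window consistency test is
  calibrated by construction (session-label permutation).
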