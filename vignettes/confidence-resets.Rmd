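---
title: "Hierarchical and flat ideal observers for change-point learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical and flat ideal observers for change-point learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
library(hierlearn)
```

## The task and its generative model

The package models a probability-learning task in which an observer watches a
long binary sequence (stimuli coded 1 and 2) and continuously estimates the
two *repetition* (transition) probabilities $\theta_{1|1} = p(1_t \mid
1_{t-1})$ and $\theta_{2|2} = p(2_t \mid 2_{t-1})$; the complementary
alternation probabilities are implied. The probabilities are piecewise
constant: stable periods are geometric with mean 75 trials (truncated by
resampling at 300, so the law stays geometric below the bound — the per-trial
change probability, the task's *volatility*, is fixed at $1/75$), and at
every change point the affected probabilities are redrawn uniformly on
$[0.1, 0.9]$ subject to the constraint that the odds ratio $p/(1-p)$ of at
least one affected probability moves at least fourfold, so each change is
behaviorally effective. In the *coupled* (main) task both probabilities share
their change points; in the *uncoupled* (control) task each changes
independently and only the affected one is redrawn, with the fold constraint
applied to it. An experiment is four blocks of 380 trials; observers treat
blocks as separate sequences.

`gen_config()` holds every one of these constants; `generate_sequence()`
draws a full experiment's stimuli together with their hidden trajectories and
change-point flags.

## The two observers

Both observers are ideal in the sense of applying Bayes' rule under their own
assumptions; they differ only in whether those assumptions include change
points.

**Hierarchical observer** (`hier_observer()`). The generative process is a
hidden Markov model on $\theta$: with probability $p_c$ per observation
$\theta$ is redrawn from the prior, otherwise it persists. Forward filtering
propagates the joint weight over a grid of $\theta$ values: each new
observation multiplies in its Bernoulli likelihood (conditioned on the
previous stimulus; the first observation of a block has constant likelihood
$1/2$), the weights are renormalized, and the change-point mixture

$$q_t(\theta) \;=\; (1 - p_c)\, p(\theta \mid y_{1:t}) \;+\; p_c\,
\mathrm{prior}(\theta)$$

is applied. All reported quantities are moments of $q_t$, the one-step-ahead
posterior $p(\theta_{t+1} \mid y_{1:t})$ — exactly the distribution that the
predictive probability of the next stimulus integrates over. This convention
makes the two limiting cases transparent: $p_c = 0$ reduces to exact
conjugate Beta updating, and $p_c = 1$ predicts $1/2$ forever. In the
coupled variant the joint over $(\theta_{1|1}, \theta_{2|2})$ is
two-dimensional and the mixture resets both dimensions together — this is
what lets a surprising streak of one stimulus *generalize* and reset the
posterior of the other, never-observed transition. The uncoupled variant is
two independent one-dimensional filters (each observation's likelihood
touches one parameter only). A frequency variant tracks a single stimulus
probability the same way.

**Flat observer** (`flat_observer()`). No representation of change points:
transition counts are kept with an exponential leak so the $k$-th past
observation weighs $e^{-k/\omega}$, Beta pseudo-counts (`prior_counts`) are
added, and the estimate and confidence are the mean and log-precision of the
implied Beta posterior. With prior counts $[0\ 0]$ the posterior mean is, as
the count sum saturates, exactly a delta rule with learning rate
$1 - e^{-1/\omega}$; with $[1\ 1]$ (Laplace) and $\omega = \infty$ it is the
rule of succession. Leakiness lets the flat observer cope with changes it
does not represent — its first-order estimates approximate the hierarchical
ones extremely well, which is precisely why first-order reports alone
discriminate the models poorly.

**Confidence** is defined identically for both observers as the
log-precision $-\ln \mathrm{Var}$ of the posterior over the transition
probability conditioned on the current stimulus. It is the second-order
readout on which the two observers genuinely differ.

### Numerical choices

* Grid: midpoints of a uniform partition of $(0,1)$, 50 points per dimension
  by default. Predictions at 100 vs 200 points differ by under $10^{-4}$
  (tested), so conclusions are grid-robust; the test suite uses 35-point
  grids where many 1520-trial filters must run, and 200 points where
  conjugate limits are checked to $10^{-3}$.
* The model prior spans all of $(0,1)$ even though generation uses
  $[0.1, 0.9]$: the observer is generic and participants are not told the
  range.
* Filtering runs in linear space with per-trial renormalization; at these
  sequence lengths and grid sizes the weights never underflow (a zero total
  mass raises an explicit error).
* Flat prior $[0\ 0]$ start: until both counts of the relevant transition
  are populated the estimate is reported as 0.5 and the confidence as `NA`
  (undefined) rather than an improper value.
* Confidence uses the natural logarithm; any other base only rescales the
  linear regressions used downstream.
* Grid-search ties break toward the smaller parameter (more forgetting) for
  exactly tied objectives.

## Fitting and model comparison

Each observer has one free parameter ($p_c$ or $\omega$), adjusted by grid
search (log-spaced defaults: $10^{-4}$–$0.5$ and $1$–$10^3$, 61 points) to
minimize squared error. `fit_to_generative()` scores the model's predictive
probability of every realized observation against its true generative
probability over all trials — fitting the observer to the task, not to a
person. `fit_to_subject_prob()` replaces generative values with a subject's
probability reports at question trials; `fit_to_subject_conf()` uses the
residual sum of squares of a per-subject linear regression of reported
confidence on model confidence, because a bounded slider and an unbounded
log-precision share no scale — only the affine-invariant residual is
meaningful. With equal parameter counts, model comparison reduces to the
paired difference of mean squared errors (`compare_models_mse()`).

## The hallmark: confidence resets after suspicious streaks

A run of seven or more identical stimuli beginning after a block's 15th
stimulus is a *streak*. A streak is *suspicious* if the coupled hierarchical
observer's confidence in the repeated transition falls on average while it
unfolds (the repetitions contradict its current estimate, so a change point
is suspected), and *non-suspicious* otherwise (`classify_streaks()`). The
coupled observer reacts to a suspicious streak by resetting its posterior
over **both** transition probabilities; the flat observer — and the
hierarchical observer of the uncoupled task, for which generalization is
wrong — lose confidence in the unobserved transition only through passive
forgetting, identically for both streak types. Pre/post questions placed on
the stimulus just before a streak begins and on the stimulus that terminates
it (both of which are the non-repeated symbol, so both probe the
non-repeating transition) turn this divergence into a measurable interaction:
the change in confidence (post minus pre), contrasted between non-suspicious
and suspicious streaks, is positive for a coupled hierarchical learner and
near zero otherwise (`pre_post_change()`, `streak_type_contrast()`).

`assemble_experiment()` rejection-samples sequences the way the experiment
was constructed: a candidate is accepted only if it holds at least 8
terminated streaks of each label with at least one of each per block, admits
a selection of 8 per label whose mean durations differ by at most 2 trials
(duration being the obvious confound of a confidence drop), and whose
selected suspicious streaks show a mean model-confidence drop of at least
0.5 log-precision units about the probed transition — the threshold behind
"the effect must be observable" is a free design constant and is exposed as
`min_conf_drop`. The 68 non-streak questions are placed quasi-periodically
(ideal slots at a mean gap of 15 trials, jittered by up to ±5 and nudged so
no random question is adjacent to any other); they are not otherwise
constrained away from streaks. The accepted design stores its seed, and
regeneration from that seed is bit-exact.

Three per-streak differences are reported. `d_conf` is the probed-transition
confidence change — the hallmark carrier. `d_prob` is the probability change
*on the report scale* (probability assigned to stimulus 1): on that scale
the sign of any estimate shift alternates with the streak symbol, so a null
streak-type contrast is the expected outcome and serves as the first-order
control. `d_dist` isolates the subtler estimate reset as the change in
distance of the probed estimate from the prior value 0.5; the hierarchical
model shows a weak positive contrast on it, subjects' reports are not
expected to resolve one. The analysis deliberately never compares subject
sliders and model log-precision raw — every subject–model confidence
relation goes through a regression.

Two further checks guard the interpretation. `residual_confidence_test()`
regresses confidence reports on z-scored first-order covariates of the
subject's own probability report — distance from 0.5, Shannon entropy of the
reported distribution, and surprise $-\log p$ at the actually observed next
stimulus (`first_order_covariates()`, a documented and replaceable set) —
and asks whether the residuals still track optimal confidence; a positive
group slope means confidence carries second-order information.
`exclusion_filter()` removes subjects whose probability reports correlate
with the optimal estimates below $\rho = 0.18$ (strictly below: 0.18 itself
stays in).

## Simulation studies

`run_lr_sim()` reproduces the fixed-parameter counter-example on the classic
single-statistic task: the *apparent learning rate*
$(\theta_{t+1}-\theta_t)/(y_{t+1}-\theta_t)$ of both observers — each with
its single parameter fitted jointly to the generative probabilities of a
low-volatility schedule (7 fixed change points) and a high-volatility
schedule (7 additional ones) — shows transient peaks after change points and
a higher mean under high volatility *in both models*, although the flat
model's parameters never move. Modulations of the apparent learning rate are
therefore not, by themselves, evidence of hierarchical processing. Default
sequences are 560 trials with change points every 70 (35) trials; positions
are configurable and the conclusions do not depend on them.

`correlation_map()` quantifies why confidence is the better discriminator:
over a grid of volatilities and odds-step sizes, each model's parameter is
fitted to the generative probabilities on training sequences and the two
fitted models are run on fresh sequences. Their pooled per-trial probability
estimates correlate above 0.9 near the experimental regime (volatility
0.013, fourfold steps) while their confidence levels correlate markedly
lower — agreement on the first order, divergence on the second. The package
default uses 25 evaluation sequences of 400 trials per cell (the full-scale
setting of 100 sequences is one argument away); at 25 sequences the pooled
correlation is stable to well under the margins at stake.

## Synthetic subjects

`generate_subject()` maps an observer trace into the nine-column per-trial
layout of the behavioral dataset (modality, block, stimulus, the two
generative transition probabilities, probability report, confidence report,
two reaction times), with reports present exactly at question trials.
Probability reports shrink the predictive probability toward 0.5 with slope
0.66 and add Gaussian noise of sd 0.18 before clipping to $[0,1]$ — a
calibration chosen so that synthetic cohorts land near the fit quality
observed in humans on this task (group regression slope ≈ 0.66, correlation
≈ 0.56); it is a description of report quality, not a claim about the true
human noise process. Confidence reports map log-precision affinely onto the
slider with slope 0.10 — mirroring the subject-versus-model confidence
regression slope observed empirically — intercept 0.1, and sd 0.15, a
plausible slider report noise. A single independent Gaussian noise source
per report is the simplest choice, and its known cost is that it cannot
simultaneously reproduce a low *global* subject–model confidence correlation
and a large *paired* streak contrast, as real subjects do: slow
session-level drifts in how people use a confidence slider inflate global
scatter while cancelling within pre/post pairs. A session-offset plus local
noise decomposition would capture that; it is deliberately out of scope
here, and group-level streak statistics from these synthetic cohorts should
be read as conservative. Reaction times are left missing (reaction-time
analyses are out of scope). `write_dataset()`/`read_dataset()` round-trip
cohorts as one plain CSV per subject in three cohort directories
(`main_included`, `main_excluded`, `control`), with `NA` as the missing
sentinel.

What passing tests on these cohorts do show: the full pipeline — sequence
selection, question placement, report generation, contrast statistics —
transmits the coupled-hierarchical signature and transmits *no* signature
for flat or uncoupled-task sources. What they cannot show: anything about
human deviations the noise model does not contain (biased probability
weighting, slider dynamics, modality effects, learning across blocks).

## Problem sizes used by the checks

The test suite runs every 1520-trial filter bank at a 35-point grid,
verifies filtering against exhaustive change-point enumeration at sequence
lengths up to 6 and a 5-point grid (where the enumeration is exact to
$10^{-10}$), checks conjugate limits at a 200-point grid on 1000 trials,
uses 23 designs per task variant with 20 synthetic-cohort draws for the
dissociation statistics, 200 repetitions for the learning-rate sign tests,
and 10 four-block experiments for volatility recovery. These sizes are the
package's choices for routine verification; every one of them is an argument
that can be turned up.

## Known limitations

* Inference over $p_c$ itself (a volatility hierarchy) is not implemented;
  $p_c$ is fixed, as is appropriate for a task with constant volatility.
* Structure learning (identifying coupled versus uncoupled change points
  from data) is out of scope.
* The deposited behavioral dataset is not shipped; analyses of it require
  exporting it into the CSV dialect described above.
* The flat-observer family is the leaky-count Beta model only; metaplastic
  or noisy-inference flat variants are not implemented.
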