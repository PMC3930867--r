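---
title: "Models and methods behind revlearn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind revlearn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`revlearn` implements trial-by-trial learning models for a two-alternative
probabilistic reversal task, together with the machinery needed to study
them end to end: a generative task simulator, softmax choice, per-participant
maximum-likelihood fitting, BIC model comparison, parameter- and
model-recovery pipelines, and reward-maximizing ("ideal agent") analyses.
This vignette is the package's own account of the science and of every
design decision that was genuinely open.

## The task

On each trial a red or blue triangle appears and the responder presses one
of two buttons. Responses are encoded as *types*: type 1 is button one for
red and button two for blue, type 2 the mirror image. The environment has a
hidden *rule* (1 or 2): the rule-consistent response type is rewarded on a
fraction of trials called the *feedback validity* (FV), 25/30 (83.3%) in
high-FV blocks and 22/30 (73.3%) in low-FV blocks. Outcomes are *coupled*:
exactly one response type is rewarded per trial, so win/loss feedback on
either response reveals both counterfactuals. Blocks of 120 trials cross
rule (2) x FV (2) x volatility (2): *stable* blocks keep one rule
throughout, *volatile* blocks switch the rule every 30 trials. The eight
conditions are each presented once, in a randomized order.

`generate_schedule()` reproduces this design. Within every constant-rule
segment the number of rule-consistent rewarded types is exactly
`round(FV * segment length)` -- 25/30 and 22/30 per volatile segment, 100
and 88 per stable block -- with positions shuffled by the seeded RNG, i.e.
outcomes are randomized *to meet the percentages exactly*, not just in
expectation. Stimulus colors are i.i.d. uniform: color is informationally
irrelevant for coupled models, and the original design gives no balancing
rule; the uncoupled learner still consumes it.

## The learning models

All models maintain a belief about which response type is currently
rewarded and update it from the revealed rewarded type (coupled models) or
from own feedback (uncoupled model).

**RL (standard coupled delta rule).** One predicted value $Q_1(t) \in
[0,1]$ for a type-1 response, initialized at $0.5$, with $Q_2 = 1 - Q_1$.
With $R(t) = 1$ if type 1 was rewarded and 0 otherwise,
$$\delta(t) = R(t) - Q_1(t), \qquad Q_1(t+1) = Q_1(t) + \alpha\,\delta(t),$$
with a single learning rate $\alpha \in [0,1]$ and a single temperature.

**WL (win/loss-split).** Identical update, but the learning rate used to
incorporate trial $t$ is $\alpha_{win}$ when trial $t$ was a win for the
responder and $\alpha_{loss}$ when it was a loss, and the softmax
temperature is likewise split ($T_{win}$ after a win, $T_{loss}$ after a
loss). *Keying decision:* "after a win" is read as keyed to the feedback
being incorporated -- the update that carries trial $t$'s outcome uses the
trial-$t$ feedback's rate, and the choice on trial $t+1$ uses the
trial-$t$ feedback's temperature. With equal win/loss parameters WL is
bit-identical to RL (tested).

**UNC (uncoupled).** Four independent action values, one per
(color, button) cell, all initialized at 0.5 (the unbiased prior under 0/1
reward coding; the source states 0.5 explicitly only for the coupled
models). Only the experienced cell updates, with $R = 1$ on a win; the
other three are carried forward without forgetting.

**HMM (two-state hidden Markov filter).** The hidden state is the rule;
both the transition kernel and the outcome likelihood are symmetric
$2\times 2$ matrices $\begin{pmatrix} p & 1-p \\ 1-p & p\end{pmatrix}$
built from $1 - p_{switch}$ and $1 - p_{error}$. The forward recursion
multiplies the transitioned posterior by the outcome likelihood and
renormalizes; the per-trial normalizers multiply to the marginal outcome
likelihood, which is what the exhaustive path-sum oracle
(`hmm_path_sum_loglik()`, all $2^t$ paths, $t \le 12$) checks to 1e-10.
*Timing decision:* the belief that informs the choice on trial $t+1$
applies one further transition beyond the posterior, i.e.
$P(X_{t+1}\mid y_{1..t})$ -- the filter anticipates a possible switch
before the next choice. Filtering is done in linear space with per-step
renormalization; with $p_{error} \ge 10^{-5}$ there is no underflow over
960 trials.

**VOL (hierarchical volatility filter).** The hidden state $X$ is the
reward probability of a type-2 response, discretized on 49 equally spaced
interior points of $(0,1)$; a second hidden variable $V$ (volatility, same
grid) controls how fast $X$ drifts; a parameter $K$ expresses confidence
in the volatility estimate. Per trial the joint propagates as
$$P(X_t,V_t,K,y_{1..t}) \propto P(y_t\mid X_t)\sum_i P(X_t\mid x^i_{t-1},V_t)
\sum_j P(V_t\mid v^j_{t-1},K)\,P(x^i_{t-1},v^j_{t-1},K,y_{1..t-1}).$$
The filter is participant-independent; only the two temperatures are
fitted.

Design decisions where the source under-determines the VOL model (the
underlying thesis is unavailable):

* **X kernel**: discretized beta densities with mean $x'$ (the previous
  value) and precision $a+b = \exp(c\,(1-v))$ with $c = 10$, so the
  smallest grid volatility gives a near-identity kernel (row SD ~0.004)
  and the largest approaches a fresh draw. Rows are renormalized over the
  grid; degenerate shapes are clipped at $10^{-8}$ with a warning.
* **V kernel**: discretized normal densities centered on $v'$ with SD $k$.
* **K grid**: 30 log-spaced points in $[0.005, 0.5]$, uniform prior,
  marginalized rather than fitted (the filter is shared across
  participants).
* **Outcome model**: Bernoulli, $P(\text{type-2 rewarded}) = x$. The
  source mentions a normal distribution for the outcome variable, which is
  not interpretable for a binary outcome and conflicts with the stated
  role of $X$ as "the probability of reward"; the Bernoulli choice is
  isolated behind `vol_kernels()`/`vol_step()` so alternatives can be
  swapped.
* **Belief timing**: the choice belief is the posterior mean
  $\mathbb{E}[X]$ from the previous update. The beta kernel is
  mean-preserving, so -- unlike the two-state HMM, where the transition
  moves the posterior toward 0.5 -- propagating before the choice would
  not change the belief materially; the posterior mean is used directly.

## Choice rule

Given a belief $B(t)$ in a type-1 response, the probability of responding
type 1 is the softmax
$$P(t) = \frac{e^{B(t)/T}}{e^{B(t)/T} + e^{(1-B(t))/T}},$$
with $T \ge 0.01$. For UNC the two displayed-color action values enter
directly (they are not complementary). Models with a temperature pair use
$T_{win}$ after a win and $T_{loss}$ after a loss; a missed previous trial
counts as a loss. On trial 1 `T_win` is used -- provably inconsequential,
since all initial beliefs are symmetric and the choice probability is 0.5
under either temperature (tested). Missed trials never update beliefs and
are excluded from likelihoods. Log-probabilities are computed with
`plogis(log.p = TRUE)`, so extreme belief/temperature combinations stay
finite.

## Fitting, comparison, recovery

`fit_participant()` maximizes the summed log choice probability of the
responses actually taken, over the box: learning rates in
$[10^{-4}, 1]$, HMM probabilities in $[10^{-5}, 0.5]$, temperatures
$\ge 0.01$. Decisions around the optimizer:

* the search caps temperatures at 20 -- beyond that the likelihood is flat
  in $T$ (responding is effectively random) and an unbounded direction
  stalls optimizers; the cap is a search setting, not a model bound;
* 10 starting points drawn uniformly over the box (the source does not
  describe its handling of local optima), refined with L-BFGS-B;
  `parscale` is set to the box widths, without which the mixed scales
  (probabilities vs temperatures) defeat the finite-difference gradient;
* fits are deterministic given `seed`; the VOL belief trajectory is
  parameter-free and computed once per dataset.

`bic()` implements $-2\log L + k \log N$ with $N$ = responded trials and
$k$ = 2, 2, 4, 4, 2 for UNC, RL, WL, HMM, VOL. Whether a cohort BIC is a
mean or a sum is ambiguous in the source; `compare_models()` reports both,
labeled. Best-model ties break toward fewer parameters (then a fixed
canonical order), Bayes factors use $\exp(\Delta BIC / 2)$.

`parameter_recovery()` and `model_recovery()` wrap simulate-refit loops;
the default "typical participant" generator values are the WL cohort
means (0.77, 0.52, 0.35, 0.87), RL (0.6, 0.5), a realistic HMM set
(0.021, 0.2, 0.35, 0.87), the degenerate HMM set
($p_{error} = 0.49$, $p_{switch} = 0.35$) whose behavior collapses onto a
slightly-biased coin tracking the last outcome (beliefs provably within
0.05 of 0.5; tested) and is therefore mimicked by RL with $\alpha = 1$ and
a high temperature at half the parameter cost, and VOL temperatures
(0.35, 0.87).

## Ideal agents

An ideal agent picks the response its model currently rates more likely to
be rewarded (no softmax) and its parameters are grid-searched to maximize
total wins: learning rates at 0.01 steps over $(0, 1]$; HMM over
$p_{switch} \in [0.005, 0.05]$ (0.005 steps, plus the generative 0.021)
and $p_{error} \in [0.1, 0.3]$ (0.01 steps), bracketing the generative
environment (switch rate 0.021 $\approx$ 5 switches in 240 trials; mean
error probability 0.22). Ties at belief exactly 0.5 -- always the first
trial -- are broken by a seeded fair coin. Schedules for ideal analyses
are freshly generated synthetic ones (default 31, one per simulated
participant): outcome sequences are response-independent under coupling,
so this is distributionally faithful even though the humans' sequences are
unavailable. The grid is evaluated with common outcome sequences across
grid points, so the win surface is a deterministic function of the
schedules.

Two numerical facts about these surfaces matter for interpretation, both
measured by the test suite:

* distinct parameter settings can induce *identical* greedy policies
  (for the HMM, $p_{switch}$ and $p_{error}$ trade off in the posterior
  odds), producing exact ties in total wins; among exact ties the point
  nearest the generative anchor is returned, mirroring the search's
  anchoring on the generative structure;
* away from exact ties the surfaces are still extremely flat along a
  ridge (depths of ~0.1 mean wins out of ~700), so the argmax
  *coordinate* has substantial sampling variance across schedule draws,
  while the RL optimum and the WL after-loss rate are stable. The
  acceptance test for the grid optima therefore checks that the published
  optimum performs within paired sampling noise of the computed argmax --
  on a flat ridge that, not the argmax coordinate, is the reproducible
  quantity.

`maximizing_curve()` aligns volatile-block segments at rule switches and
reports the percentage of rule-consistent responses by post-switch
position, split by FV. Softmax WL simulation at the cohort-mean fitted
parameters plateaus near each block's feedback validity (probability
matching); the greedy ideal WL instead approaches 100% in high-FV blocks.

## What the synthetic generator does and does not establish

The generator reproduces the *design*: exact within-segment reward
counts, the 2x2x2 block structure, switch spacing, coupled feedback, and
(optionally) missed trials at a configurable rate, since the human miss
rate is unreported (default 0). It does not emulate reaction times, reward
magnitudes (points are reduced to win/loss by design), sequential color
balancing, drifting strategies, or between-participant heterogeneity
beyond what parameter sets express. A green acceptance suite therefore
establishes that the *models, estimators and analyses* behave as published
on data from the stated generative world -- not that human parameter
values are recoverable from the unavailable behavioral dataset; cohort
Table-level BICs and human maximizing percentages are out of scope for the
same reason.

## Known limitations

* The VOL kernel constants ($c$, the K grid) are package design choices;
  other settings satisfying the same qualitative roles would change VOL
  fits quantitatively.
* HMM parameters are poorly identified from single participants (error
  probability trades off against temperature); this is a property of the
  model family, reproduced -- not fixed -- here.
* The ideal-agent argmax coordinates on flat ridges are reported honestly
  and carry the sampling variance discussed above.
* The CLI exchanges configuration as JSON (no YAML dependency in the
  supported stack).
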