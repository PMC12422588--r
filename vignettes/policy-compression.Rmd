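---
title: "Capacity-limited policies over partial action consideration sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Capacity-limited policies over partial action consideration sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(policompress)
```

## The model

A contextual bandit task is a state distribution $P(s)$ together with a
reward matrix $Q(s,a)$. An agent's policy $\pi(a\mid s)$ earns
trial-averaged reward

$$V_\pi = \sum_s P(s) \sum_a \pi(a\mid s)\, Q(s,a),$$

and carries a cognitive cost formalized as the mutual information between
states and actions — the *policy complexity*,

$$I_\pi(S;A) = \sum_s P(s)\sum_a \pi(a\mid s)\,
  \log\frac{\pi(a\mid s)}{P(a)},
  \qquad P(a) = \sum_s P(s)\,\pi(a\mid s).$$

Maximizing $V_\pi$ subject to $I_\pi(S;A) \le C$ is a rate-distortion
problem. Its solution has the self-consistent form

$$\pi^*(a\mid s) \propto \exp\left[\beta\, Q(s,a) + \log P^*(a)\right],$$

where $\beta \ge 0$ is the Lagrange multiplier attached to the capacity
$C$, and $P^*$ is the optimal policy's own marginal. Iterating this update
together with the marginal is the Blahut–Arimoto (BA) algorithm
(`blahut_arimoto()`). Sweeping $\beta$ and recording
$(I_\pi, V_\pi)$ traces the *reward-complexity frontier*
(`trace_frontier()`): the maximal reward attainable at each complexity.
The frontier is concave, non-decreasing, and its slope in natural-log
units at the point traced by $\beta$ is $1/\beta$. At $\beta = 0$ the
optimal policy is a state-independent point mass on the action with the
highest *general value* $V(a) = \sum_s P(s) Q(s,a)$; this endpoint is
computed analytically (`zero_complexity_endpoint()`) because the BA
update is degenerate there (every state-independent policy is
stationary); ties break toward the lowest action index.

The second resource the package models is the *action consideration set*:
instead of optimizing over all actions, the agent samples a subset from a
proposal distribution $P_0(a)$ — flat, proportional to general value, or
the oracle marginal $P^*(a)$ — and solves the reduced problem obtained by
deleting the excluded reward columns (`restrict_task()`). The gap between
what the restricted policy earns and the full-action-space frontier at
the same complexity (`reward_loss()`) quantifies the suboptimality that
the consideration set induces.

When actions are sampled *with replacement*, the draw frequencies carry
information that BA ignores. The self-normalized importance-sampling
estimator (`snis_policy()`) instead reweights each sampled action by
$\mathrm{count}(a) / P_0(a)$ inside the BA-style fixed point,
producing an asymptotically unbiased estimate of the *full-action-space*
optimal policy at the same $\beta$. The optimal marginal appearing in the
weights is unavailable to an agent, so the estimator's own marginal
replaces it and the update is iterated to a fixed point; when every
action appears exactly once under a flat proposal the weights cancel and
the fixed point coincides with BA exactly.

## Numerical choices

* **Log domain.** All row normalizations use log-sum-exp, so large
  $\beta |Q|$ cannot underflow a state row; probabilities that underflow
  to zero simply drop out of the support ($\log 0 = -\infty$ is handled
  exactly). Complexities are computed in nats and reported in bits.
* **Convergence.** A BA/SNIS solve stops when the largest absolute policy
  change in one sweep falls below `tol` (default `1e-10`, cap `10000`
  sweeps); a capped run returns the current iterate flagged with a
  warning rather than failing.
* **Warm-started tracing.** `trace_frontier()` solves its grid in
  ascending $\beta$ order, starting each solve from the previous solution
  mixed with $10^{-8}$ of the uniform policy (a pure warm start could
  carry exact zeros forward and lock actions out of later solves). The
  problem is convex, so this changes nothing about the solution — but it
  cures the critical slowing down near the task's phase transitions,
  where a cold-started solve can need orders of magnitude more sweeps,
  and it makes the traced curve numerically monotone at `1e-9`. The
  tracing tolerance is tightened to `1e-12` for the same reason.
* **Default $\beta$ grid.** 60 geometrically spaced values in
  $[0.05, 50]$ plus the analytic $\beta = 0$ endpoint. Geometric spacing
  matches the frontier's geometry: its slope is $1/\beta$, so equal
  multiplicative steps in $\beta$ give roughly even coverage of the
  curve.
* **Evaluating "on or below the frontier".** Between traced knots, chord
  interpolation (`frontier_reward_at()`) *under*-estimates the concave
  frontier, which can make a perfectly legal point look like it lies
  above the curve by the chord gap (up to $\sim 10^{-3}$ near the
  high-curvature elbow). Dominance checks therefore use the
  supporting-line bound (`frontier_reward_bound()`): each traced point
  contributes the tangent of slope $\log 2/\beta$ (bits), and the
  minimum over tangents never dips below the true frontier.
* **Negative general values.** User-supplied tasks can have
  $V(a) \le 0$, which would break the general-value proposal; the vector
  is shifted by $-\min V + 10^{-6}\,\mathrm{range}(V)$ before
  normalization. The shift preserves the ranking and is inert on all
  built-in tasks, whose general values are positive.
* **Sampling without replacement** uses sequential weighted draws with
  renormalization over the remaining actions (base R's weighted
  `sample()`), the natural scheme when none is prescribed.

## Built-in tasks and the synthetic-data generator

Four task constructors cover the study conditions:

* `make_symmetric_task(n)` — one uniquely optimal action per state
  (rewards 1/0 by default), flat $P(s)$; used for exact, enumerable
  analyses.
* `make_random_task(16, 32, seed)` — i.i.d. Uniform(0,1) rewards. The
  uniform law is a deliberate choice where only "random entries" is
  specified: it keeps all general values positive (so the general-value
  proposal needs no shift) and gives mild, realistic spread in $V(a)$.
* `make_scarce_task()` — reward concentrated on a few "rich" columns
  (Uniform(0.5, 1) against Uniform(0, 0.05)); the exact recipe for such
  tasks is not canonical, so the ranges are parameters.
* `make_experiment_task()` — the 6-state/7-action task of the behavioral
  paradigm: each state's unique optimal action pays $+1$, the other
  unsafe actions $-0.18$, and a seventh *safety* action pays $+0.2$ in
  every state. Its zero-complexity endpoint is exactly $0.2$, and the
  deterministic optimal mapping earns exactly $1$. The paradigm's
  timeout penalty punishes *not responding*, so it is not part of
  $Q(s,a)$.

`simulate_agent()` is the synthetic stand-in for behavioral data: it
draws per-trial states (counterbalanced so the empirical $P(s)$ is flat,
as in blocked designs, or i.i.d.), samples actions from a known policy,
and reads rewards off $Q$. It emulates a stationary agent with a fixed
policy and exact reward delivery; it does **not** model learning within
a block, response times, lapses or motor errors. Tests passing on this
generator therefore validate the estimators *given* the model class, not
the model's fit to real humans.

## Estimating behavior

Given a trial log, `estimate_policy()` smooths the per-state action
counts with a symmetric Dirichlet prior and returns the posterior-mean
policy,

$$\hat\pi(a \mid s) = \frac{n_{sa} + \alpha}{n_s + N_a \alpha},$$

and `estimate_complexity()` reports the mutual information of that
policy under the empirical state frequencies. The default
$\alpha = 0.01$ is chosen so that empirical (complexity, reward) points
from frontier-following agents stay at or below the frontier — with too
little smoothing the plug-in mutual information overshoots, and the
point can appear super-optimal. The literature this estimator descends
from describes a posterior *expected* mutual information; the procedure
implemented here is the plug-in information of the posterior-mean
policy, which is what the present methods actually compute, and the
$\alpha$ calibration compensates at these sample sizes. Empirical state
frequencies (not the design distribution) weight the estimate, which
matters only when schedules are not counterbalanced. The consideration
set size is estimated by `count_actions()`: the number of distinct
actions chosen at least `min_count` times (2 or 3 discards likely key
slips).

## The simulation suites

`run_suite()` sweeps proposals × three algorithm/sampling regimes (BA
without replacement over set sizes $N_a$; SNIS with replacement over
draw counts $n$; BA with replacement over $n$) × a $\beta$ grid, with
`n_reps` Monte-Carlo replicates per cell aggregated as mean ± SEM of
complexity, reward and frontier loss. The reference replication count is
200 per cell; the packaged tests run 50, which resolves the qualitative
orderings while keeping a desk-scale run under a few minutes.

Replicate seeds derive deterministically from the master seed, the
(task, sampling regime, size, $\beta$) cell and the replicate index —
deliberately *not* from the proposal kind or algorithm. Conditions that
differ only in those two therefore see identical random draws (common
random numbers), so the comparisons the sweep exists for — flat vs
general-value proposals, BA vs SNIS at matched samples — are paired,
which removes most Monte-Carlo variance from their differences without
affecting any marginal distribution.

`noisy_q_suite()` models imperfect value learning: each replicate smears
$Q$ with Gaussian noise, the agent picks its consideration set using the
*noisy* general values (safety action forced in or out by rule) and
optimizes against the noisy values, while being scored on the true task.
The choice to sample the set from the noisy general-value proposal — the
same heuristic the clean suite studies — keeps the agent model coherent
across suites; it is one reasonable reading of an agent "selecting its
own consideration set", and the qualitative conclusion (loss at low
complexity grows with noise, and larger sets can amplify it) does not
depend on it. Perturbed tasks drop the safety marker, since the noisy
safety column is no longer state-independent.

## A worked example

```{r frontier, eval = FALSE}
task <- make_experiment_task()
frontier <- trace_frontier(task)
head(frontier$points, 3)

# restrict to the safety action plus one unsafe action
rt <- restrict_task(task, c(1, 7))
pol <- blahut_arimoto(rt, beta = 50)
full <- expand_policy(pol, attr(rt, "parent_actions"), n_actions(task))
reward_loss(task, full, frontier)  # strictly negative: 2 actions cannot
                                   # match the 7-action frontier
```

## Problem sizes used in the packaged checks

The test suite traces full frontiers for the experiment task and the
16×32 random task on the default 60-point grid; enumerates all
$2^7 - 1$ consideration sets of the experiment task on a reduced
15-point grid; runs the proposal/algorithm comparisons at 50 replicates,
set size 2 and $\beta = 0.05$; and runs the noisy-value suite at 50
replicates over four noise levels. These sizes were chosen as the
smallest at which the qualitative contrasts are resolved with paired
sampling; the package itself has no such limits.

## Known limitations

* The mapping $C \leftrightarrow \beta$ has no closed form and is not
  inverted; all frontier work is parameterized by $\beta$ on a fixed
  grid, with no adaptive refinement between grid points.
* Optimal consideration-*set search* is out of scope: the package
  evaluates sampled or enumerated sets, it does not optimize over them
  (exhaustive enumeration is guarded at $10^5$ subsets).
* States and actions are discrete and rewards deterministic per
  $(s,a)$; continuous spaces and stochastic rewards are not modeled.
* `simulate_agent()` produces stationary synthetic choices only; none of
  the regression-style analyses applied to human cohorts are
  implemented here.
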