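---
title: "A dual-system model of hippocampal and dorsolateral-striatal learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A dual-system model of hippocampal and dorsolateral-striatal learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualnav)
```

## The model

`dualnav` simulates an agent whose behavior is the reliability-weighted
combination of two valuation systems with qualitatively different learning
strategies.

**The hippocampal system** learns a *successor representation* (SR): a matrix
$M^\pi(s, s')$ of expected discounted future occupancies,
$M^\pi(s,s') = E_\pi\left[\sum_t \gamma^t I(s_t = s') \mid s_0 = s\right]$,
together with a reward vector $R$ learned by a delta rule. Value factorizes as
$V(s) = \sum_{s'} M(s,s')\,R(s')$, so when the reward moves, relearning $R$
alone instantly revalues every state — the mechanism behind fast, flexible,
allocentric "place" behavior. Action values come from one-step lookahead,
$Q_{HPC}(s,a) = \hat R(s) + \gamma\, E[V(s') \mid s,a]$, using the known grid
adjacency in arenas and the true transition probabilities in task graphs.
$M$ is learned by temporal-difference updates on the successor prediction
error $\delta^M(s') = I(s{=}s') + \gamma M(s_{t+1},s') - M(s_t,s')$. In large
or cue-defined state spaces the same system runs over *successor features*:
place-cell rates $f(s)$ replace state indicators, a weight matrix $W$
approximates $\psi(s) = W^\top f(s)$, and reward weights $u$ give
$V = \psi^\top u$.

**The dorsolateral-striatal system** is model-free: linear Q-learning over
egocentric sensory features with eligibility traces. Landmark cells (LCs)
are tuned to a landmark of a specific identity at a preferred egocentric
distance and bearing (a bivariate Gaussian in $(d, \theta)$, peak 1); the
striatal action axis is likewise egocentric (turns relative to heading), so
what this system learns is a stimulus–response habit that transfers across
allocentric contexts — the basis of "response" behavior and of its
insensitivity to reward devaluation.

**The arbitrator** tracks each system's reliability as one minus the recent
average of its absolute prediction errors
($\Delta\Omega = \eta(|\delta| - \Omega)$, $\chi = (\delta_{max} -
\min(\Omega, \delta_{max}))/\delta_{max}$), converts the reliabilities into
logistic transition rates $\alpha(\chi_{MF})$ and $\beta(\chi_{SR})$, and
integrates a push–pull dynamics on the SR system's influence,
$dP_{SR}/dt = \alpha(1 - P_{SR}) - \beta P_{SR}$. The combined action values
are $Q_{net} = P_{SR} Q_{HPC} + (1-P_{SR}) Q_{DLS}$ — values are mixed, not
actions — and a softmax draws the action. Lesions and inactivations are
clamps on $P_{SR}$: a hippocampal lesion pins it toward 0, a striatal lesion
toward 1.

```{r linear-track}
track <- build_arena("linear_track", n = 5)
set.seed(1)
agent <- make_spatial_agent(track, agent_config(max_steps = 50))
psr <- latency <- numeric(30)
for (t in 1:30) {
  rec <- run_trial(agent, track)
  psr[t] <- mean(rec$psr); latency[t] <- rec$steps
}
round(rbind(latency = latency, P_SR = psr)[, c(1:6, 26:30)], 2)
```

On the linear track the SR system leads early (its random-walk prior from
reward-free preexposure predicts states well) and cedes control as the
striatal reward predictions sharpen — the signature arbitration trajectory.

## Design choices that required a decision

Several components are specified only loosely by the phenomena the model
targets; the choices made here, and why:

* **Reliability updating.** The SR system's state-prediction error exists on
  every step, so $\Omega_{SR}$ updates every step (rate `eta`). The
  model-free system's reward-prediction error is only informative at
  outcomes: updating $\Omega_{MF}$ on every step would score the system
  "reliable" for predicting nothing during long unrewarded stretches of a
  water-maze trial and collapse $P_{SR}$ before any reward is ever seen.
  $\Omega_{MF}$ therefore updates at outcome events (terminal or rewarded
  steps, rate `eta_mf`); the $P_{SR}$ dynamics still step every environment
  step.
* **Eligibility-trace increment.** Only the executed action's traces are
  strengthened, by the feature vector itself (`e[, a] <- e[, a] + f`), the
  Watkins convention. Gating the increment by the action's own activation
  would make learning impossible from zero-initialized weights.
* **Terminal transitions.** The striatal bootstrap is 0 at terminal states.
  The SR bootstrap at a terminal transition is the absorbing state's
  one-hot (the goal predicts its own occupancy and nothing after), and the
  absorbing state's own row is relaxed toward that one-hot — otherwise the
  preexposure prior's self-occupancy at the goal ($\approx 1/(1-\gamma)$)
  is never corrected and inflates hippocampal values by an order of
  magnitude.
* **Bounded bootstraps and normalized steps.** Rewards are episodic
  Bernoulli($\le 1$), so true action values lie in $[0, 1]$; the model-free
  max-bootstrap is clipped to that range (off-policy Q($\lambda$) over
  overlapping features otherwise inflates values it never acts on). The
  successor-feature and reward-weight updates divide by
  $\max(1, \lVert f\rVert^2)$ (a normalized-LMS step), which is inert for
  one-hot features — the tabular and feature-based learners coincide
  exactly there, a property the test suite asserts.
* **Action masking.** Moves into walls are clipped no-ops at the
  environment level; at selection time they are masked, because a
  selectable no-op lets the max-bootstrap feed Q(no-op)
  $\leftarrow \gamma \max_a Q(\text{same state})$ and deadlock the agent at
  junctions.
* **Zero-distance landmarks.** An LC's bearing is undefined when the agent
  stands on its landmark; the whole bank is silent there. Letting every
  angle-tuned cell fire instead creates a heading-invariant feature blob
  that inherits "cue-behind, turn-around" habits and produces spurious
  reversals at maze junctions.
* **Arbitration rates.** $A_\alpha = 1$, $B_\alpha = 6$, $A_\beta = 0.3$,
  $B_\beta = 1$: transitions toward the SR system are suppressed sharply
  once the model-free system becomes reliable (the bias toward the cheaper
  system), while the reverse rate is weakly modulated. The crossing point
  sits near $\chi_{MF} \approx 0.36$, which places the plus-maze
  place-to-response switch in mid-training; much steeper settings hand
  control to the striatum almost immediately.

## Parameters

All of these live in `agent_config()`; distances are in grid cells, one
time step is one environment step.

| parameter | default | role |
|---|---|---|
| `gamma` | 0.95 | discount; sets how far value gradients reach |
| `alpha_q`, `lambda` | 0.1, 0.9 | striatal Q learning rate and trace decay |
| `alpha_m` | 0.3 | SR / successor-feature learning rate |
| `alpha_r` | 0.3 | reward-representation learning rate |
| `eta`, `eta_mf` | 0.01, 0.015 | reliability averaging rates (SR per step; MF per outcome) |
| `A_alpha`, `B_alpha`, `A_beta`, `B_beta` | 1, 6, 0.3, 1 | arbitration transition rates |
| `beta_softmax` | 20 | inverse temperature (8 on the two-step task, whose value scale is coarser) |
| `psr_bounds` | [0, 1] | lesion clamps on the SR influence |
| `max_steps` | 300 | trial step cap (capped trials are flagged) |

## The simulated protocols

* **Adapted water maze** (`run_pearce()`): 11 sessions of 4 trials on a
  20×20 pool (15×15 in the correlation study); platform and landmark move
  jointly between sessions with a fixed offset. Control agents relearn the
  reward vector within a session (trial 4 ≪ trial 1) but linger at the
  previous platform on trial 1 — their occupancy, accumulated in a
  previous-platform-centered frame, peaks within 2 cells of it.
  Hippocampus-lesioned agents navigate by the landmark: faster first
  trials, flat within-session learning.
* **Plus maze** (`run_plus_maze()`): 60 training trials from a fixed start
  arm; probe trials from the opposite arm after trials 28 and 60 classify
  each agent as using a place strategy (trained goal arm) or a response
  strategy (same egocentric turn). Inactivations are applied at probe time
  on a frozen copy of the trained agent, as in the modeled infusion
  experiments; devaluation scales the hippocampal reward representation
  (striatal weights untouched) before the probe.
* **Blocking** (`run_blocking()`): three 10-trial phases (single cue,
  compound, first cue removed). In the landmark condition behavior is
  striatally controlled and removal of the trained landmark reveals
  blocking of the added one. In the boundary condition place cells are
  driven by boundary-vector cells from the pool enclosure plus the two
  removable inner walls; the successor-feature weights let cells driven by
  the added boundary come to predict the reward-associated cells, so no
  blocking appears.
* **Two-step task** (`run_two_step()`): the standard two-stage structure
  with common transitions at 0.7 and outcome reward probabilities drifting
  as a bounded Gaussian random walk in [0.25, 0.75]. (One figure caption in
  the source literature transposes "common" and "rare"; the implementation
  uses common = 0.7, the standard design.) The striatal arm shows a reward
  main effect, the hippocampal arm the reward-by-transition crossover, the
  full model both.
* **Correlation study** (`run_correlation_study()`): 20 intact agents with
  heterogeneous arbitration parameters and 20 agents with a partial
  hippocampal lesion ($P_{SR}$ clamped to [0, 0.02]) each run the two-step
  task (1200 trials; model-based index = reward-by-transition interaction
  of a stay logistic regression, lightly ridge-stabilized so perseverative
  agents remain estimable) and the water-maze protocol (place-memory score
  = mean distance from the previous platform to the net value-map argmax
  at next-session start). Heterogeneity is sampled as
  $A_\alpha \sim \log U(0.02, 3)$, $B_\alpha \sim U(2, 5)$,
  $B_\beta \sim U(0.25, 3)$, inverse temperature $\sim U(7.5, 8.5)$.
  $A_\alpha$ — the amplitude of the transition rate toward the SR system —
  is the deliberately shared trait: it expresses the same
  hippocampal-versus-striatal disposition in both tasks, which is exactly
  what the cross-task association measures. Two wider alternatives were
  rejected on mechanism: wide $B_\alpha$ sampling acts as a
  trait-by-task interaction (the two tasks settle at different model-free
  reliability levels, so steepness sends the same agent to different
  systems in different tasks), and wide temperature sampling couples the
  two measures through policy sharpness alone (sharper agents have both
  crisper striatal value peaks and larger apparent planning indices),
  producing a spurious association even in fully lesioned agents.

## What the synthetic environments do and do not emulate

All inputs are generated internally: arenas are uniform square grids with
8-direction moves and clipped walls, swimming dynamics and continuous
motion are not modeled, trial "latency" is a step count, and reward is
binary. Landmarks are point cues with identity; boundaries are line
segments sampled at a fixed arc step for the BVC integral. These
abstractions preserve the structure the model explains — which coordinate
frame carries the predictive load, and which errors drive each learner —
but quantitative latencies, learning-curve shapes and effect sizes are not
calibrated to any animal dataset; passing tests show the mechanisms
produce the qualitative dissociations, not that the model fits rodent
numbers.

Problem sizes in the test suite and acceptance script (8–20 agents per
arm, 15–20-cell grids, 200–1200 trials) were chosen as the smallest runs
at which the reported contrasts are stable across seeds.

## Statistics

Stay probabilities condition on the previous trial's reward and transition
type. The model-based index is the interaction coefficient of
`stay ~ reward * transition` (both coded ±1) per agent. Cross-task
association uses the Fisher transform, $z = \tanh^{-1}(r)\sqrt{n-3}$;
two arms are compared by the standard Fisher difference statistic
(cross-checked against a permutation oracle in the tests), one-sided where
the direction is predicted in advance. Blocking is a one-sided paired
t-test of the phase-3 minus phase-2 escape-time contrast across agents.
A caveat worth stating: with n = 20 agents per arm, a single correlation's
Fisher z has a sampling SD near 1, so individual-run z values scatter
widely around their expectation; the qualitative pattern (intact positive
and significant, lesioned null) is the stable result.

## Known limitations

The temporal-difference SR cannot revalue after *transition* changes
without re-experience; no replay or offline updating is modeled. The SR is
policy-dependent, so the learned map reflects the training policy. The
arbitration parameters are declared defaults, not values fitted to
behavioral data. The one-step lookahead uses the generative environment
model rather than a learned one. Heading is discretized to the 8 movement
directions, and landmark-cell tuning widths do not scale with distance.
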