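---
title: "Active-inference navigation with a dynamically expanding cognitive map"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Active-inference navigation with a dynamically expanding cognitive map}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cognav)
```

## The problem

An agent is dropped into a maze of colored rooms it has never seen: it knows
neither the maze's size, nor its color alphabet, nor its own location.  Each
step it perceives only the floor color of its current room and which of the
four sides are walls, and may move North/East/South/West or stay.  Colors may
repeat across rooms ("aliasing"), so observations alone do not identify a
location.  The agent must localize itself, learn the maze's connectivity, and
navigate to preferred observations — and keep doing so when the world changes
under it (new obstacles, silent teleportation).

`cognav` implements an active-inference agent for this task.  Its defining
feature is that the cognitive map grows over *predicted* locations: every
door of a visited room immediately spawns a hypothetical neighboring state,
so planning can reason about places the agent has never been.

## Generative model

The agent maintains Dirichlet pseudo-counts for three likelihoods over a
growing state space $s$, observation alphabet $o$, and position table $p$:

* $A_o = P(o \mid s)$ — which color a state emits;
* $A_p = P(p \mid s)$ — which internal position a state occupies;
* $B_s = P(s_t \mid s_{t-1}, a)$ — state transitions per action.

Positions are integer offsets from the exploration origin $(0,0)$ and evolve
through a *deterministic* map $B_p(p, a)$: moving East from $(0,0)$ yields
$(1,0)$ whenever the side is believed open, and `Stay` is the identity.  The
same determinism is mirrored in $B_s$'s `Stay` slice.  Probabilities are
Dirichlet means: `normalize(counts)`.

State inference is a one-step variational filter.  In normal operation

$$q(s_t) \propto P(o_t \mid s_t)\, \tilde P(p_t \mid s_t) \sum_{s'} P(s_t \mid s', a_{t-1})\, q(s'),$$

where $\tilde P(p \mid s)$ is the position likelihood tempered by a
proprioceptive-reliability mixture (below).  The step's variational free
energy `compute_vfe()` is $E_q[\log q - \log P]$; it equals the negative log
evidence exactly when $q$ is the step posterior, which the test suite checks
on an enumerable two-state toy.

### Map expansion over predictions

After each confident perception, `imagine_frontier()` sweeps the four sides
of the current room.  A wall adds an imagined self-transition count and
suppresses the corresponding $B_p$ edge; an open side predicts the
neighboring position, growing the position table if the position is new and
creating a new state bound to it (so $P(s \mid p)$ is one-hot at the
binding) if no state lives there.  The new state's observation column stays
at the base count, i.e. uniform: the agent cannot predict what it will see
there, and exactly that uncertainty is what makes frontiers attractive to
the planner.  Imagined transition counts use the imagined rate
$\eta_{im} = 0.2$, with a half-rate reverse count so the planner can route
*through* imagined states without asserting them; experienced crossings use
$\eta_{exp} = 1$ in both directions.  Experienced links therefore always
dominate their imagined precursors.

### Negative learning

A collision observed where the map believes a door (a newly placed obstacle)
triggers `negative_update()`: the evidence behind the believed transition is
removed in proportion to the agent's confidence — entirely, at certainty —
floored at the base count, and the position edge is suppressed.  The removed
evidence is forgotten rather than banked on the self-transition; the
self-loop belief for walls comes from the imagination sweep.  This keeps
revision fast (one contradiction at full confidence flips the belief however
strongly the door had been reinforced) while preserving plasticity: a single
later re-experience of the door restores it.

## Planning by expected free energy

Candidate policies are built by construction, not enumeration: one shortest
action sequence per state reachable within the horizon under argmax
dynamics, plus `Stay`.  This keeps 14-step horizons cheap (tens of
candidates instead of $5^{14}$).  Every candidate is padded with `Stay` to
the common horizon so policies of different lengths are compared over the
same number of predicted steps.

Each policy's expected free energy $G$ sums, per predicted step:

* **state information gain** — the mutual information between predicted
  state and predicted observation, i.e. the expected KL from prior to
  posterior state belief;
* **parameter information gain** — Dirichlet novelty of the observation and
  transition counts the step would touch, using the standard half-inverse
  count difference $\tfrac12(1/\alpha_k - 1/\alpha_0)$; never-observed
  (imagined) states and unconfirmed doors score highest;
* **utility** — expected log preference of the predicted observation.  The
  preference is a softmax with logit $w$ on the preferred color, shifted so
  a uniform preference scores exactly zero; with $w = 0$ utility vanishes
  identically and exploration is driven by information gain alone;
* **collision risk** — the probability of stepping into a remembered wall,
  times a fixed penalty (4), the binary-collision risk term.

Actions are sampled from $\sigma(-\gamma G)$ and only the first action is
executed; the agent re-plans every step.

Two numerical choices matter here.  First, the planner's *predictive*
distributions (transition rollouts and predicted observations) renormalize
the evidence counts with the base pseudo-count removed; a column without
evidence predicts uniformly (observations) or staying (transitions).  With
the base count left in, a 14-step rollout diffuses toward uniform and
long-horizon imagination is impossible, while inference, learning and the
map statistic below always use the full Dirichlet mean.  Second, novelty
weights are computed from the raw counts, so the sharpening never hides how
little a column has been observed.

## Confidence gating and getting lost

Confidence is the posterior maximum.  Below 0.5 the agent declares itself
lost: the position factor is dropped ("observation-only" inference), the
pose estimate freezes, and all model updates pause.  Above 0.7 it recovers,
re-anchoring its pose to the most likely state's bound position.  The
hysteresis between the two thresholds prevents mode flapping.

For a kidnapping to be *detectable* the position factor cannot be absolute:
it is mixed with a uniform floor,
$\tilde P(p \mid s) = (1-\lambda) P(p \mid s) + \lambda / P$, with
$\lambda = 0.3$.  At this value one confidently learned, uniquely
identifying color outweighs a stale pose (likelihood ratios of order 30:1
against a pose prior of order $\lambda/P$), while under aliasing the pose
factor still dominates observation ties by roughly 50:1.  Model updates
additionally require that the inferred state's bound pose agrees with the
pose estimate, so the window between displacement and re-anchoring cannot
write inconsistent structure into the map.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `epsilon` | 0.03 | base pseudo-count per Dirichlet cell |
| `eta_exp` | 1.0 | experienced learning rate |
| `eta_im` | 0.2 | imagined learning rate (reverse: half) |
| `eta_neg` | 1.0 | negative-learning proportion at full confidence |
| `kappa_bind` | 1000 | pose-state binding count (`P(s|p)` ≥ 0.99) |
| `pose_noise` | 0.3 | proprioceptive-reliability mixture |
| `conf_threshold` / `recover_threshold` | 0.5 / 0.7 | lost-mode hysteresis |
| `gamma` | 8 | softmax temperature (2 in the Tolman protocol) |
| `horizon` | 14 | planning depth |
| `utility_weight` | 0 (explore) / 2 (goal) | preference logit |
| `collision_penalty` | 4 | risk-term weight |

The base count deserves its own paragraph.  The map-learning criterion
(below) requires every true door transition to be believed with probability
at least 0.6, and the learning design assumes a single experienced crossing
dominates its column.  With $S$ states a column carries $\epsilon(S-1)$
background mass, so the largest supported maze (23 rooms) bounds
$\epsilon$: at $\epsilon = 0.03$ one crossing normalizes to
$1.33/(1.33 + 0.66) \approx 0.67$, which clears the floor with margin; at
$\epsilon = 0.1$ it would normalize to $0.44$ and every door would need two
crossings.  0.03 is the largest round value satisfying the worst case.

## Experiment protocols and what they show

* **Exploration** (`run_exploration_suite`): pure information-gain runs
  terminating at the first step where `map_confidence()` passes — all rooms
  visited and every true door transition believed at ≥ 60%.  The exact
  coverage oracle (`min_coverage_steps`, a breadth-first search over
  room × visited-set states) is the per-start lower bound; no run can beat
  it, and the suites check none does.  Default scale: 20 runs per
  environment, which keeps the full acceptance sweep to a few minutes.
* **Goal reaching** (`run_goal_suite`): a preferred color with $w = 2$; a
  goal counts only on a deliberate terminal `Stay`.  With a learned map the
  step counts match the shortest-path oracle; without one the agent
  searches systematically first.
* **Tolman protocol** (`run_tolman_protocol`): three series (no obstacle,
  block on the shortest route's own segment, block on the segment shared by
  the two shorter routes) of 12 attempts per agent, silent repositioning to
  the start every 20 steps, memory retained throughout.  Route choice is
  classified by the last route-distinguishing room visited before the goal,
  and obstacle-series counts start at the agent's first contact with the
  blockage.  The protocol uses $\gamma = 2$: route alternation is a
  stochastic-selection phenomenon and the greedier exploration temperature
  would suppress it.
* **Donut remapping** (`run_donut_remapping`): learn the ring, kidnap to a
  corner, seal the short-path room mid-plan.  The verdict requires reaching
  the goal the long way with at most 5 collisions; disabling negative
  learning makes the agent bump indefinitely, which the ablation control
  verifies.

## What the simulator does and does not emulate

The room worlds are deterministic grids with per-room colors and symmetric
door/wall sides; void cells model non-rectangular shapes (T, donut, the
Tolman maze) and a room sealed on all sides models a closed-off chamber.
Observations are noiseless and collisions are sensed only from adjacent
rooms.  Real perception pipelines add observation noise, continuous motion
within rooms, and imperfect odometry — none of which are modeled, so passing
tests here demonstrates the mapping/planning layer, not robustness of
perception.  Two consequences are worth naming: with a noiseless unique
color, re-localization after kidnapping can be immediate; and because the
pose estimate is a point anchored by a near-one-hot binding, aliased colors
cost the agent nothing *during* undisturbed exploration — divided confidence
appears only when displacement breaks the pose prior, as in the aliased
T-maze demonstration.

## Known limitations

* States discovered to be duplicates (two internal poses for one physical
  room, possible after long odometry-free confusion) are never merged; loop
  closure beyond position identity is out of scope.
* The coverage oracle's exact search is limited to 20 rooms; for the
  23-room Tolman maze only shortest-path oracles are used.
* Policies are shortest paths to targets; worlds where the optimal
  information-gathering route is not a shortest path to any single state
  would need richer policy construction.
* One-step filtering, not smoothing: past beliefs are never revised
  retrospectively.
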