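# cognav

Active-inference navigation with a dynamically expanding cognitive map.

`cognav` is for researchers in computational neuroscience and robotics who
study spatial cognition: it provides a complete, inspectable implementation
of an agent that learns the layout of room-structured mini-grid mazes while
navigating them — without knowing the maze's size, color alphabet, or its
own starting location — together with the maze simulator, exact oracle
baselines, and the behavioral experiment protocols (exploration efficiency,
goal reaching, Tolman-style insight rerouting, dynamic remapping after
blockages and kidnappings).

## The model in brief

The agent holds Dirichlet counts for an observation likelihood
`A_o = P(o|s)`, a position likelihood `A_p = P(p|s)`, and action-conditioned
state transitions `B_s = P(s'|s,a)`, alongside a deterministic position map
`B_p(p,a)` over integer pose offsets from the exploration origin.  Each step
it filters its state belief

```
q(s_t) ∝ P(o_t|s_t) · P̃(p_t|s_t) · Σ_s' P(s_t|s',a) q(s')
```

and then — this is the core idea — *expands the map over predictions*: every
open door of the current room spawns a position, and a state bound to it, in
the model before the agent has ever been there.  Plans are scored by
expected free energy

```
G(π) = Σ_τ [ −info_gain(state) − info_gain(parameters) − utility + risk ]
```

and sampled through a tempered softmax `P(π) = σ(−γ G(π))`; imagined states
carry uniform observation columns, so they dominate the information-gain
terms and exploration is systematically frontier-directed.  Collisions that
contradict a believed door trigger confidence-proportional negative
learning, which is what lets the agent re-plan promptly when a known passage
is blocked.  A confidence gate (posterior maximum below 0.5) handles
kidnapping: position information is suspended, learning pauses, and the
agent re-localizes from observations alone.

See `vignette("cognitive-map-navigation")` for the full model description,
parameter table, and design rationale.

## Worked example

```r
library(cognav)

lay <- maze_fixture("3x3")
lay
#> room_layout '3x3': 3x3 grid, 9 rooms, 9 colors, 9 doors

ep <- run_episode(lay, config = cognav_config(),
                  termination = "map", budget = 200, seed = 42)
ep$steps; ep$reason
#> [1] 11
#> [1] "map-learned"

min_coverage_steps(lay)   # exact lower bound: visit all 9 rooms from this start
#> [1] 11
```

This run learned the whole maze in 11 steps — here equal to the oracle's
minimum coverage walk, i.e. no wasted movement.  The episode ends at the
first step where every true door transition is believed with probability at
least 0.6:

```r
mc <- map_confidence(ep$model, lay, room_state_map(ep$model, lay, c(0, 1)))
round(mc$confidence, 3)
#> [1] 0.847

head(cognitive_edges(ep$model), 4)
#>    from to action probability
#> N     1  2      N   0.8644068
#> E     1  3      E   0.9163763
#> E1    2  8      E   0.8471338
#> S     2  1      S   0.8562874
```

`cognitive_edges()`/`cognitive_graph()` expose the learned map as an edge
list or `igraph` object (writable as GraphML); `write_model()` snapshots the
full count tensors to JSON.

Higher-level protocols wrap this loop: `run_exploration_suite()` (seeded
batches against the oracle bound), `run_goal_suite()` (navigate to a
preferred floor color, with or without a previously learned map),
`run_tolman_protocol()` (three obstacle series with silent repositioning
every 20 steps), and `run_donut_remapping()` (blockage mid-plan, with a
negative-learning ablation control).  A thin command-line front end over
these lives in `inst/scripts/cognav.R`.

## Environments

Eleven fixtures ship under `inst/extdata/` in a plain-text layout format
(color grid plus two door/wall gate grids; `maze_fixture()` loads them,
`load_layout()`/`write_layout()` parse and serialize arbitrary ones):
`3x3`, `3x3_alias`, `4x4`, `4x4_alias`, `T_maze`, `T_maze_alias`, `Donuts`,
`Donuts_blocked`, `Tolman`, `Tolman_A`, `Tolman_B`.  The aliased variants
repeat floor colors across rooms; the Tolman variants carry the two
classical blockage positions.

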