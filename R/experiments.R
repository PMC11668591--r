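#' Exploration suite
#'
#' Seeded pure-exploration episodes (`utility_weight = 0`): each run starts
#' at one of the fixture's recorded spawn poses and ends at the first step
#' where the learned transition beliefs pass [map_confidence()].  Reports
#' steps-to-learn, steps-to-discover-all-rooms, and the exact oracle bound
#' for each run's start.
#'
#' @param env fixture name (see [maze_fixture()]) or a `room_layout`.
#' @param n_runs number of episodes.
#' @param seed integer master seed; run `i` uses `seed + 97 * i`.
#' @param config a [cognav_config()]; forced to pure exploration.
#' @param budget per-episode step budget; episodes that exhaust it are
#'   flagged and excluded from the means with a warning.
#' @return list with `runs` (one row per episode: seed, start, steps,
#'   discovered_at, oracle, success) and `summary` (mean/sd of
#'   steps-to-learn and discovery steps over successful runs, mean oracle).
#' @export
run_exploration_suite <- function(env, n_runs = 20, seed = 1,
                                  config = cognav_config(), budget = 400L) {
  layout <- if (inherits(env, "room_layout")) env else maze_fixture(env)
  config$utility_weight <- 0
  config$pref_color <- NULL
  starts <- layout$starts
  if (!length(starts)) stop("fixture has no recorded start poses")
  rows <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    rs <- seed + 97L * i
    set.seed(rs)
    st <- starts[[sample.int(length(starts), 1L)]]
    ep <- run_episode(layout, start = st, config = config,
                      termination = "map", budget = budget)
    rows[[i]] <- data.frame(
      run = i, seed = rs, start_x = st[1], start_y = st[2],
      steps = if (ep$success) ep$steps else NA_integer_,
      discovered_at = ep$discovered_at,
      oracle = min_coverage_steps(layout, st),
      success = ep$success)
  }
  runs <- do.call(rbind, rows)
  if (any(!runs$success))
    warning(sum(!runs$success), " exploration run(s) hit the step budget; ",
            "excluded from the means")
  ok <- runs$success
  list(runs = runs,
       summary = data.frame(
         env = layout$name, n = sum(ok),
         mean_steps = mean(runs$steps[ok]), sd_steps = stats::sd(runs$steps[ok]),
         mean_discovery = mean(runs$discovered_at[ok]),
         mean_oracle = mean(runs$oracle)))
}

#' Goal-reaching suite
#'
#' Navigation toward a preferred observation (a floor color).  With
#' `with_prior = TRUE` each run first explores the maze, is then kidnapped
#' to a spawn pose with its map kept in memory, and navigates to the goal;
#' without prior it starts fresh.  A goal counts as reached only on a
#' deliberate terminal Stay at the goal color.
#'
#' @param env fixture name or `room_layout`.
#' @param goal_color preferred color; must exist in the layout.
#' @param with_prior pre-learn the map before the goal run?
#' @param n_runs,seed as in [run_exploration_suite()].
#' @param utility_weight weight on the EFE utility term during goal runs.
#' @param config base [cognav_config()].
#' @param budget goal-run step budget.
#' @return list with `runs` (steps, oracle shortest path from each run's
#'   start, success) and `summary`.
#' @export
run_goal_suite <- function(env, goal_color, with_prior = TRUE, n_runs = 20,
                           seed = 1, utility_weight = 2,
                           config = cognav_config(), budget = 400L) {
  layout <- if (inherits(env, "room_layout")) env else maze_fixture(env)
  if (!goal_color %in% layout$color_names) stop("goal color not in layout")
  starts <- layout$starts
  rows <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    rs <- seed + 97L * i
    set.seed(rs)
    st <- starts[[sample.int(length(starts), 1L)]]
    model <- NULL; belief <- NULL
    if (with_prior) {
      cfg_ex <- config
      cfg_ex$utility_weight <- 0; cfg_ex$pref_color <- NULL
      ex <- run_episode(layout, start = st, config = cfg_ex,
                        termination = "map", budget = budget)
      model <- ex$model; belief <- ex$belief
      # kidnap: restart somewhere else, memory kept, belief uninformed of it
      st <- starts[[sample.int(length(starts), 1L)]]
    }
    cfg <- config
    cfg$utility_weight <- utility_weight
    cfg$pref_color <- goal_color
    ep <- run_episode(layout, start = st, config = cfg, termination = "goal",
                      budget = budget, goal_color = goal_color,
                      model = model, belief = belief)
    rows[[i]] <- data.frame(
      run = i, seed = rs, start_x = st[1], start_y = st[2],
      steps = if (ep$success) ep$steps else NA_integer_,
      oracle = shortest_path_steps(layout, st, goal_color),
      success = ep$success)
  }
  runs <- do.call(rbind, rows)
  ok <- runs$success
  list(runs = runs,
       summary = data.frame(
         env = layout$name, goal = goal_color, with_prior = with_prior,
         n = sum(ok), mean_steps = mean(runs$steps[ok]),
         sd_steps = stats::sd(runs$steps[ok]),
         mean_oracle = mean(runs$oracle[ok]),
         mean_excess = mean(runs$steps[ok] - runs$oracle[ok])))
}

# rooms that distinguish each Tolman route (reconstruction geometry)
tolman_route_markers <- function() {
  list(
    "1" = c("3,2", "3,3"),
    "2" = c("4,1", "5,1", "5,2", "5,3", "5,4", "4,4"),
    "3" = c("2,1", "1,1", "0,1", "0,2", "0,3", "0,4", "0,5", "0,6", "1,6", "2,6"))
}

# blocked-edge adjacency per series: rooms from which the blockage is felt,
# with the direction whose collision flag reveals it
tolman_block_sides <- function(series) {
  switch(series,
    A = list(c("3,2", "N"), c("3,3", "S")),
    B = list(c("3,4", "N"), c("3,5", "S")),
    NULL)
}

#' Tolman-maze protocol
#'
#' Replays the latent-learning protocol: each agent runs three series (no
#' obstacle, block A on the Route-1 segment, block B on the segment shared
#' by Routes 1 and 2) of `runs_per_series` goal attempts in the Tolman
#' fixture, keeping its memory across runs and series.  Every attempt starts
#' at the bottom of the maze (a silent repositioning); an attempt ends on a
#' deliberate Stay at the goal color or after `kidnap_every` steps.
#' Completions are classified by the last route-distinguishing room visited
#' before the goal and, for the obstacle series, counted only after the
#' agent has first felt the blockage (its collision flag from an adjacent
#' room).
#'
#' @param n_agents number of independent agents.
#' @param runs_per_series goal attempts per obstacle condition.
#' @param kidnap_every steps between silent repositionings.
#' @param utility_weight weight on the goal preference.
#' @param horizon planning horizon.
#' @param gamma softmax temperature (lower than the exploration default to
#'   reproduce stochastic path alternation).
#' @param seed master seed; agent `a` uses `seed + 991 * a`.
#' @return list with `counts` (per series, completions via Routes 1/2/3)
#'   and `detail` (per agent/series/run rows).
#' @export
run_tolman_protocol <- function(n_agents = 10, runs_per_series = 12,
                                kidnap_every = 20, utility_weight = 2,
                                horizon = 14, gamma = 2, seed = 1) {
  markers <- tolman_route_markers()
  goal <- "red"
  series_names <- c("none", "A", "B")
  layouts <- list(none = maze_fixture("Tolman"), A = maze_fixture("Tolman_A"),
                  B = maze_fixture("Tolman_B"))
  counts <- matrix(0L, 3, 3, dimnames = list(series_names, c("1", "2", "3")))
  detail <- list()
  for (ag in seq_len(n_agents)) {
    set.seed(seed + 991L * ag)
    cfg <- cognav_config(utility_weight = utility_weight, pref_color = goal,
                         horizon = horizon, gamma = gamma)
    model <- NULL; belief <- NULL
    for (series in series_names) {
      layout <- layouts[[series]]
      blocked_felt <- is.null(tolman_block_sides(series))
      for (rep in seq_len(runs_per_series)) {
        run <- start_run(layout, start = c(3, 0), config = cfg,
                         model = model, belief = belief)
        trace <- character(0)
        route <- NA_character_
        completed <- FALSE
        while (run$steps < kidnap_every) {
          run_step(run, goal_color = goal)
          if (!blocked_felt)
            for (bs in tolman_block_sides(series)) {
              if (paste0(run$pose[1], ",", run$pose[2]) == bs[1] &&
                  run$obs$collisions[[bs[2]]]) blocked_felt <- TRUE
            }
          key <- paste0(run$pose[1], ",", run$pose[2])
          for (r in names(markers)) if (key %in% markers[[r]]) route <- r
          if (run$goal_reached) { completed <- TRUE; break }
        }
        if (completed && !is.na(route) && blocked_felt)
          counts[series, route] <- counts[series, route] + 1L
        detail[[length(detail) + 1L]] <- data.frame(
          agent = ag, series = series, rep = rep, steps = run$steps,
          completed = completed, route = route, counted = completed &&
            !is.na(route) && blocked_felt)
        model <- run$model; belief <- run$belief
      }
    }
  }
  list(counts = counts, detail = do.call(rbind, detail))
}

#' Donut remapping scenario
#'
#' The agent first learns the Donut ring, is kidnapped to a corner with a
#' light-pink goal color, takes one planned step along the short path, and
#' then the short-path room is sealed on all sides.  The verdict passes when
#' the goal is still reached — via the long way round — with at most
#' `bump_budget` collisions after the blockage, which requires the negative
#' parameter learning to revise the sealed passage; with
#' `negative_learning = FALSE` the agent keeps believing the old map.
#'
#' @param seed integer seed.
#' @param negative_learning toggle for the ablation control.
#' @param bump_budget tolerated number of post-blockage collisions.
#' @param budget goal-run step budget.
#' @return list with `verdict`, `steps`, `bumps`, `reached`, `log`.
#' @export
run_donut_remapping <- function(seed = 1, negative_learning = TRUE,
                                bump_budget = 5, budget = 80L) {
  set.seed(seed)
  layout <- maze_fixture("Donuts")
  goal <- "pink"
  cfg_ex <- cognav_config()
  ex <- run_episode(layout, start = c(4, 3), config = cfg_ex,
                    termination = "map", budget = 400L)
  cfg <- cognav_config(utility_weight = 2, pref_color = goal,
                       negative_learning = negative_learning)
  run <- start_run(layout, start = c(0, 0), config = cfg,
                   model = ex$model, belief = ex$belief)
  run_step(run, goal_color = goal)          # first move along the short path
  run$layout <- modify_world(run$layout, "seal-room", c(2, 0))
  bumps0 <- run$bumps
  while (!run$goal_reached && run$steps < budget) run_step(run, goal_color = goal)
  bumps <- run$bumps - bumps0
  list(verdict = run$goal_reached && bumps <= bump_budget,
       reached = run$goal_reached, steps = run$steps, bumps = bumps,
       log = run_log(run))
}
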