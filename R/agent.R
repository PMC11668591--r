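#' Start an agent run
#'
#' Creates the mutable run state for one episode: the world (layout + true
#' pose), the agent (model + belief), and the run log.  The agent perceives
#' the initial observation, growing a fresh model from it when none is
#' given; passing a `model`/`belief` from an earlier episode continues with
#' that memory (e.g. after a kidnapping).
#'
#' @param layout a `room_layout`.
#' @param start world start pose `c(x, y)`; defaults to the layout's first
#'   recorded start.
#' @param config a [cognav_config()].
#' @param model,belief optional prior memory.
#' @return an environment of class `cognav_run`.
#' @export
start_run <- function(layout, start = NULL, config = cognav_config(),
                      model = NULL, belief = NULL) {
  if (is.null(start)) {
    if (!length(layout$starts)) stop("layout has no recorded start pose")
    start <- layout$starts[[1]]
  }
  run <- new.env(parent = emptyenv())
  class(run) <- "cognav_run"
  run$layout <- layout
  run$pose <- as.integer(start)
  run$start <- as.integer(start)
  run$config <- config
  run$steps <- 0L
  run$bumps <- 0L
  run$log <- list()
  run$visited <- character(0)
  run$goal_reached <- FALSE
  run$obs <- observe_world(layout, run$pose)

  if (is.null(model)) {
    model <- new_model(run$obs$color_name, config)
    belief <- new_belief(model)
  } else {
    model$config <- config
    if (!(run$obs$color_name %in% model$colors))
      model <- grow_support(model, "observation", color = run$obs$color_name)
    if (is.null(belief)) belief <- new_belief(model)
  }
  belief <- update_belief(belief, model, NULL, run$obs)
  belief <- check_confidence(belief, model, config)
  s0 <- which.max(belief$q)
  pose_ok <- is.na(model$state_pose[s0]) ||
    model$state_pose[s0] == belief$pose_idx
  if (belief$mode == "normal" && belief$confidence >= config$conf_threshold &&
      pose_ok)
    model <- imagine_frontier(model, belief, run$obs)
  run$model <- model
  run$belief <- sync_belief(belief, model)
  run$prev_state <- if (belief$confidence >= config$conf_threshold)
    which.max(belief$q) else NA_integer_
  run$visited <- paste0(run$pose[1], ",", run$pose[2])
  log_step(run, action = "init")
  run
}

#' @export
print.cognav_run <- function(x, ...) {
  cat(sprintf("cognav_run: step %d at (%d,%d), %d states, mode %s\n",
              x$steps, x$pose[1], x$pose[2], n_states(x$model), x$belief$mode))
  invisible(x)
}

log_step <- function(run, action, probs = NA_real_) {
  b <- run$belief
  run$log[[length(run$log) + 1L]] <- data.frame(
    step = run$steps, x = run$pose[1], y = run$pose[2],
    action = action, color = run$obs$color_name, moved = run$obs$moved,
    mode = b$mode, confidence = b$confidence, entropy = belief_entropy(b),
    n_states = n_states(run$model), n_obs = n_obs(run$model),
    n_poses = n_poses(run$model), stringsAsFactors = FALSE)
  invisible(run)
}

#' Run log as a data frame
#' @param run a `cognav_run`.
#' @export
run_log <- function(run) do.call(rbind, run$log)

#' One perceive-learn-plan-act cycle
#'
#' Executes exactly one cycle of the agent's control loop: plan (enumerate
#' candidate policies, score them by expected free energy, sample one and
#' take its first action), act in the world, perceive (grow the observation
#' support on a novel color, update the belief, gate on confidence), and —
#' in normal mode only — revise contradicted passages, expand the map over
#' the predicted neighborhood, and learn the experienced transition.  While
#' lost, no count tensor changes and actions are chosen on observation-only
#' beliefs.
#'
#' @param run a `cognav_run`.
#' @param goal_color optional color name: if the sampled action is Stay
#'   while observing this color, the run is flagged `goal_reached` and the
#'   terminal Stay is not executed or counted.
#' @return the chosen action, invisibly.
#' @export
run_step <- function(run, goal_color = NULL) {
  config <- run$config
  model <- run$model
  belief <- run$belief

  ctx <- plan_context(model, config)
  pols <- enumerate_policies(belief, model, config$horizon)
  G <- vapply(pols, function(p)
    expected_free_energy(p, belief, model, config, ctx)$total, 0)
  sel <- select_action(pols, G, config$gamma)
  action <- sel$action

  if (!is.null(goal_color) && action == "Stay" &&
      run$obs$color_name == goal_color) {
    run$goal_reached <- TRUE
    return(invisible(action))
  }

  res <- step_world(run$layout, run$pose, action)
  run$pose <- res$pose
  run$obs <- res$obs
  run$steps <- run$steps + 1L
  if (action != "Stay" && !res$obs$moved) run$bumps <- run$bumps + 1L
  run$visited <- union(run$visited, paste0(run$pose[1], ",", run$pose[2]))
  if (is.null(run$discovered_at) &&
      length(run$visited) == sum(!run$layout$void) - n_sealed(run$layout))
    run$discovered_at <- run$steps

  if (!(res$obs$color_name %in% model$colors))
    model <- grow_support(model, "observation", color = res$obs$color_name)

  prev_conf_state <- run$prev_state
  belief <- update_belief(belief, model, action, res$obs)
  belief <- check_confidence(belief, model, config)

  s_now <- which.max(belief$q)
  # model updates require a confident state whose bound pose agrees with the
  # pose estimate; after an unnoticed displacement the two disagree until
  # the pose is re-anchored, and updates stay paused in the meantime
  pose_ok <- is.na(model$state_pose[s_now]) ||
    model$state_pose[s_now] == belief$pose_idx
  if (belief$mode == "normal" && belief$confidence >= config$conf_threshold &&
      pose_ok) {
    # negative parameter learning: a collision where this state's side was
    # believed open contradicts the map
    if (config$negative_learning) {
      for (d in c("N", "E", "S", "W")) {
        if (res$obs$collisions[[d]] && believed_open(model, s_now, d))
          model <- negative_update(model, s_now, d, belief$confidence)
      }
    }
    model <- imagine_frontier2(model, belief, res$obs)
    if (res$obs$moved && !is.na(prev_conf_state) && prev_conf_state != s_now) {
      model <- learn_from_transition(model, prev_conf_state, action, s_now,
                                     res$obs$color_name)
    } else {
      # stationary perception still reinforces the observation likelihood
      cid <- match(res$obs$color_name, model$colors)
      model$A_o[cid, s_now] <- model$A_o[cid, s_now] + config$eta_exp
    }
    run$prev_state <- s_now
  } else {
    run$prev_state <- NA_integer_
  }

  run$model <- model
  run$belief <- sync_belief(belief, model)
  log_step(run, action)
  invisible(action)
}

# imagine_frontier with the negative-learning ablation honored: when
# negative learning is disabled the agent refuses to revise a side it
# already believed open, so a fresh contradiction leaves the map untouched.
imagine_frontier2 <- function(model, belief, obs) {
  skip <- character(0)
  if (!model$config$negative_learning) {
    s <- which.max(belief$q)
    skip <- Filter(function(d) obs$collisions[[d]] && isFALSE(model$walls[s, d]),
                   c("N", "E", "S", "W"))
  }
  imagine_frontier(model, belief, obs, skip = skip)
}

n_sealed <- function(layout) {
  rooms <- which(!layout$void, arr.ind = TRUE)
  if (nrow(rooms) <= 1L) return(0L)
  sum(apply(rooms, 1, function(rc) {
    !any(vapply(c("N", "E", "S", "W"),
                function(a) has_door(layout, rc[1] - 1L, rc[2] - 1L, a), TRUE))
  }))
}

#' Kidnap the agent
#'
#' Teleports the true pose without signaling the agent: its belief, pose
#' estimate and model are untouched, and the next perception is whatever the
#' new room offers.
#'
#' @param run a `cognav_run`.
#' @param pose new world pose `c(x, y)`.
#' @export
kidnap_run <- function(run, pose) {
  run$pose <- modify_world(run$layout, "kidnap", pose)
  invisible(run)
}

#' Run a full episode
#'
#' Drives [run_step()] until termination.  Terminations:
#' * `"map"` — exploration is complete at the first step where
#'   [map_confidence()] passes (all rooms carry states and every true door
#'   transition is believed with at least `min_confidence`);
#' * `"goal"` — the agent deliberately Stays at a room showing `goal_color`
#'   (stumbling through it does not count); the terminal Stay is not counted
#'   as a step;
#' * `"budget"` — run for exactly `budget` steps.
#' Hitting `budget` under the other terminations is a failure outcome (log
#' intact).
#'
#' @param layout a `room_layout`.
#' @param start world start pose; defaults to the layout's first start.
#' @param config a [cognav_config()].
#' @param termination `"map"`, `"goal"` or `"budget"`.
#' @param budget maximum number of steps.
#' @param seed optional integer seed; the run is then fully reproducible
#'   (world dynamics are deterministic, the seed governs policy sampling).
#' @param goal_color goal color for `"goal"` termination.
#' @param model,belief optional prior memory (see [start_run()]).
#' @param min_confidence pass floor for `"map"` termination.
#' @return list with `steps`, `success`, `reason`, `discovered_at` (step at
#'   which all rooms had been physically visited, or `NA`), `log`, `model`,
#'   `belief`, `run`.
#' @export
run_episode <- function(layout, start = NULL, config = cognav_config(),
                        termination = c("map", "goal", "budget"),
                        budget = 500L, seed = NULL, goal_color = NULL,
                        model = NULL, belief = NULL, min_confidence = 0.6) {
  termination <- match.arg(termination)
  if (!is.null(seed)) set.seed(seed)
  if (termination == "goal" && is.null(goal_color))
    stop("goal termination needs goal_color")
  run <- start_run(layout, start, config, model, belief)
  success <- FALSE; reason <- "budget"
  repeat {
    if (termination == "map") {
      mc <- map_confidence(run$model, layout,
                           room_state_map(run$model, layout, run$start),
                           min_confidence)
      if (mc$pass) { success <- TRUE; reason <- "map-learned"; break }
    }
    if (run$steps >= budget) {
      success <- termination == "budget"
      reason <- if (success) "budget-complete" else "budget-exhausted"
      break
    }
    run_step(run, goal_color = if (termination == "goal") goal_color else NULL)
    if (run$goal_reached) { success <- TRUE; reason <- "goal-stay"; break }
  }
  list(steps = run$steps, success = success, reason = reason,
       discovered_at = run$discovered_at %||% NA_integer_,
       log = run_log(run), model = run$model, belief = run$belief, run = run)
}
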