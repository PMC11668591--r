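#' Expand the cognitive map over the predicted neighborhood
#'
#' The core structure-learning move: from the current room, the agent
#' considers every door as possibly leading to an un-visited room.  For each
#' direction, a perceived wall adds an imagined self-transition and marks the
#' position transition as blocked; an open side predicts the neighboring
#' pose, growing the position support, creating (and pose-binding) a new
#' state if no state lives there yet, and strengthening the imagined
#' transition at the imagined learning rate (with a weaker reverse count, so
#' planning can route through imagined states without asserting them).  The
#' new state's observation column stays uniform: the agent cannot predict
#' what it will see there.
#'
#' Expansion requires normal mode; callers pause it while lost.
#'
#' @param model a `cognav_model`.
#' @param belief a `cognav_belief` in normal mode.
#' @param obs the current `step_result` (its collision flags are the border
#'   signal for the current room).
#' @param skip directions to leave untouched (used by the negative-learning
#'   ablation, which refuses to revise a side already believed open).
#' @return the expanded model.
#' @export
imagine_frontier <- function(model, belief, obs, skip = character(0)) {
  stopifnot(belief$mode == "normal")
  s <- which.max(belief$q)
  p <- belief$pose_idx
  eta <- model$config$eta_im
  for (d in setdiff(c("N", "E", "S", "W"), skip)) {
    model$walls[s, d] <- obs$collisions[[d]]
    if (obs$collisions[[d]]) {
      model$B_s[s, s, d] <- model$B_s[s, s, d] + eta
      model$B_p[p, d] <- -1L
    } else {
      pp <- model$poses[p, ] + c(DX[[d]], DY[[d]])
      pi2 <- pose_index(model, pp)
      if (is.na(pi2)) {
        model <- grow_support(model, "position", pose = pp, from = p, action = d)
        pi2 <- n_poses(model)
      } else {
        model$B_p[p, d] <- pi2
        back <- model$B_p[pi2, opposite_action(d)]
        if (is.na(back) || back < 0) model$B_p[pi2, opposite_action(d)] <- p
      }
      s2 <- model$pose_state[pi2]
      if (is.na(s2)) {
        model <- grow_state(model)
        s2 <- n_states(model)
        model <- bind_pose_to_state(model, pi2, s2)
      }
      model$B_s[s2, s, d] <- model$B_s[s2, s, d] + eta
      od <- opposite_action(d)
      model$B_s[s, s2, od] <- model$B_s[s, s2, od] + eta / 2
    }
  }
  model
}

#' Learn from an experienced room transition
#'
#' A confidently inferred crossing `s_prev --action--> s_now` updates the
#' Dirichlet counts at the experienced learning rate, bi-directionally (the
#' reverse transition gets the same increment), and reinforces the observed
#' color at the arrival state.
#'
#' @param model a `cognav_model`.
#' @param s_prev,s_now state indices before and after the crossing.
#' @param action the crossing direction.
#' @param color the color name observed at `s_now`.
#' @return the updated model.
#' @export
learn_from_transition <- function(model, s_prev, action, s_now, color) {
  eta <- model$config$eta_exp
  model$B_s[s_now, s_prev, action] <- model$B_s[s_now, s_prev, action] + eta
  od <- opposite_action(action)
  model$B_s[s_prev, s_now, od] <- model$B_s[s_prev, s_now, od] + eta
  cid <- match(color, model$colors)
  if (is.na(cid)) stop("color outside A_o support")
  model$A_o[cid, s_now] <- model$A_o[cid, s_now] + eta
  model
}

#' Negative parameter learning after a contradicted passage
#'
#' When a collision is observed where the model believed a door (a new
#' obstacle), the evidence for the transition toward the believed neighbor
#' is removed in proportion to `eta_neg` times the agent's confidence in the
#' contradicted state — complete removal at full certainty, partial revision
#' under uncertainty — floored at the base pseudo-count; the removed mass is
#' forgotten rather than banked on the self-transition (the wall self-loop
#' is reinforced separately by imagination), the position-transition edge is
#' suppressed and the wall is memorized.  One to a few contradictions
#' therefore flip the believed successor to "stay" however strongly the
#' passage had been reinforced, while a single later re-experience of the
#' door restores the positive belief (no absorbing state).
#'
#' @param model a `cognav_model`.
#' @param s state whose outgoing passage is contradicted.
#' @param action the blocked direction.
#' @param confidence the posterior confidence backing the contradiction.
#' @return the updated model.
#' @export
negative_update <- function(model, s, action, confidence = 1) {
  eps <- model$config$epsilon
  cnt <- model$B_s[, s, action]
  nb <- order(cnt, decreasing = TRUE)
  nb <- nb[nb != s][1]
  if (length(nb) && !is.na(nb)) {
    c0 <- model$B_s[nb, s, action]
    drop <- min(1, model$config$eta_neg * confidence)
    model$B_s[nb, s, action] <- max(c0 - drop * (c0 - eps), eps)
  }
  model$walls[s, action] <- TRUE
  p <- model$state_pose[s]
  if (!is.na(p)) model$B_p[p, action] <- -1L
  model
}

#' Does the model currently believe a passage is open?
#'
#' TRUE when the argmax successor of `(s, action)` is a different state with
#' at least one imagined update of evidence behind it.
#' @param model a `cognav_model`.
#' @param s state index.
#' @param action direction.
#' @export
believed_open <- function(model, s, action) {
  cnt <- model$B_s[, s, action]
  s2 <- which.max(cnt)
  floor <- model$config$epsilon + model$config$eta_im / 2 - 1e-9
  s2 != s && cnt[s2] >= floor
}

#' Map-completeness score against the ground truth
#'
#' Exploration is considered complete when, for every true door transition
#' of the environment, the learned transition probability to the correct
#' next state reaches the confidence floor (0.6 by default).  The
#' correspondence between internal states and true rooms is established by
#' the harness from the exploration trace (the agent never sees it).
#'
#' @param model a `cognav_model`.
#' @param layout the ground-truth `room_layout`.
#' @param state_of_room named integer vector mapping room keys `"x,y"` to
#'   internal states (see [room_state_map()]).
#' @param min_confidence the pass floor.
#' @return list with `confidence` (the minimum probability over all true
#'   door transitions; 0 if some room has no state yet), `pass`, and
#'   `coverage_deficit` (rooms without a corresponding state).
#' @export
map_confidence <- function(model, layout, state_of_room, min_confidence = 0.6) {
  rooms <- which(!layout$void, arr.ind = TRUE)
  deficit <- character(0)
  probs <- numeric(0)
  for (i in seq_len(nrow(rooms))) {
    x <- rooms[i, 1] - 1L; y <- rooms[i, 2] - 1L
    key <- paste0(x, ",", y)
    s <- state_of_room[key]
    if (is.na(s)) { deficit <- c(deficit, key); next }
    for (a in c("N", "E", "S", "W")) {
      if (!has_door(layout, x, y, a)) next
      key2 <- paste0(x + DX[[a]], ",", y + DY[[a]])
      s2 <- state_of_room[key2]
      if (is.na(s2)) { deficit <- c(deficit, key2); next }
      probs <- c(probs, trans_likelihood(model, a)[s2, s])
    }
  }
  deficit <- unique(deficit)
  conf <- if (length(deficit)) 0 else if (!length(probs)) 1 else min(probs)
  list(confidence = conf, pass = conf >= min_confidence,
       coverage_deficit = deficit)
}

#' Internal-state/room correspondence from an exploration trace
#'
#' Maps every true room to the internal state bound at the corresponding
#' internal pose, using the fact that internal pose offsets mirror world
#' offsets from the episode's start room (valid for episodes without
#' kidnapping).  Harness-side only.
#'
#' @param model a `cognav_model`.
#' @param layout a `room_layout`.
#' @param start the episode's world start pose `c(x, y)`.
#' @return named integer vector over room keys `"x,y"`; `NA` where the
#'   model has no state yet.
#' @export
room_state_map <- function(model, layout, start) {
  rooms <- which(!layout$void, arr.ind = TRUE)
  keys <- paste0(rooms[, 1] - 1L, ",", rooms[, 2] - 1L)
  out <- rep(NA_integer_, length(keys))
  names(out) <- keys
  for (p in seq_len(n_poses(model))) {
    s <- model$pose_state[p]
    if (is.na(s)) next
    # only states with observation experience count as visited: a merely
    # imagined state must not satisfy the coverage requirement
    if (max(model$A_o[, s]) <= model$config$epsilon) next
    key <- paste0(start[1] + model$poses[p, 1], ",", start[2] + model$poses[p, 2])
    if (key %in% keys) out[key] <- s
  }
  out
}
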