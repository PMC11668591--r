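#' Belief state
#'
#' The agent's categorical posterior over model states, its internal pose
#' point estimate, and the confidence mode.  While `mode == "lost"` the
#' position factor is dropped from inference, the pose is frozen, and the
#' structure-learning operations are paused.
#'
#' @param model a `cognav_model`.
#' @return a list of class `cognav_belief` with `q` (posterior over states,
#'   sums to 1), `pose_idx` (index into the model's pose table), `mode`
#'   (`"normal"` or `"lost"`) and `confidence` (`max(q)`).
#' @export
new_belief <- function(model) {
  q <- rep(0, n_states(model)); q[1] <- 1
  structure(list(q = q, pose_idx = 1L, mode = "normal", confidence = 1),
            class = "cognav_belief")
}

#' @export
print.cognav_belief <- function(x, ...) {
  cat(sprintf("cognav_belief: %d states, argmax %d (%.3f), mode %s\n",
              length(x$q), which.max(x$q), x$confidence, x$mode))
  invisible(x)
}

#' Posterior entropy (nats)
#' @param belief a `cognav_belief`.
#' @export
belief_entropy <- function(belief) {
  q <- belief$q[belief$q > 0]
  -sum(q * log(q))
}

#' Pad a belief to a grown model's state dimension
#'
#' New states enter with zero posterior mass until evidence arrives.
#' @param belief a `cognav_belief`.
#' @param model a `cognav_model`.
#' @export
sync_belief <- function(belief, model) {
  S <- n_states(model)
  if (length(belief$q) < S) belief$q <- c(belief$q, rep(0, S - length(belief$q)))
  belief
}

#' One-step variational belief update
#'
#' In normal mode the posterior combines the transition prior with both the
#' observation and the position likelihood,
#' `q(s) ~ P(o|s) P(p|s) sum_s' P(s|s',a) q(s')`, and the pose point
#' estimate advances through the deterministic position map when the action
#' crossed a door.  In lost mode the position factor is dropped (the agent
#' suspends reliance on position to re-localize from observations alone) and
#' the pose is frozen.  An observation with zero total likelihood triggers a
#' uniform fallback and lost mode.
#'
#' @param belief a `cognav_belief`.
#' @param model a `cognav_model`; the observed color must already be in the
#'   observation support (callers grow first).
#' @param action the action that led to this observation (or `NULL` for the
#'   initial observation).
#' @param obs a `step_result`; `obs$moved` is the proprioceptive signal that
#'   a room transition occurred.
#' @return the updated, normalized belief.
#' @export
update_belief <- function(belief, model, action, obs) {
  S <- n_states(model)
  q <- belief$q
  if (length(q) < S) q <- c(q, rep(0, S - length(q)))  # states grown since

  if (!is.null(action) && belief$mode == "normal" && isTRUE(obs$moved)) {
    nxt <- model$B_p[belief$pose_idx, action]
    if (!is.na(nxt) && nxt > 0) belief$pose_idx <- nxt
  }

  prior <- if (is.null(action)) rep(1 / S, S) else
    as.vector(trans_likelihood(model, action) %*% q)
  cid <- match(obs$color_name, model$colors)
  if (is.na(cid)) stop("observation outside A_o support; grow first")
  lik <- obs_likelihood(model)[cid, ]
  post <- prior * lik
  if (belief$mode == "normal")
    post <- post * pose_factor(model, belief$pose_idx)

  if (sum(post) <= .Machine$double.xmin) {
    belief$q <- rep(1 / S, S)
    belief$mode <- "lost"
  } else {
    belief$q <- post / sum(post)
  }
  belief$confidence <- max(belief$q)
  belief
}

# Position factor P(p|s) tempered by proprioceptive reliability: mixed with
# a uniform floor so that an observation which plainly contradicts the pose
# (e.g. after a kidnapping) can pull the posterior away from the bound state
# and let the confidence drop.
pose_factor <- function(model, pose_idx) {
  lam <- model$config$pose_noise
  (1 - lam) * pos_likelihood(model)[pose_idx, ] + lam / n_poses(model)
}

#' Confidence gating between normal and lost mode
#'
#' Confidence below `conf_threshold` switches to lost mode (and callers
#' freeze learning); a lost agent whose confidence has recovered above
#' `recover_threshold` returns to normal mode with its pose re-anchored to
#' the most likely state's bound pose.  The hysteresis between the two
#' thresholds avoids mode flapping.
#'
#' @param belief a `cognav_belief`.
#' @param model a `cognav_model`.
#' @param config a [cognav_config()].
#' @return the belief with `mode` (and possibly `pose_idx`) updated.
#' @export
check_confidence <- function(belief, model, config = model$config) {
  if (belief$mode == "normal" && belief$confidence < config$conf_threshold) {
    belief$mode <- "lost"
  } else if (belief$confidence >= config$recover_threshold) {
    # recovery from lost mode, or a confident re-localization that
    # contradicts the current pose estimate: re-anchor the pose to the most
    # likely state's bound position
    belief$mode <- "normal"
    anchor <- model$state_pose[which.max(belief$q)]
    if (!is.na(anchor)) belief$pose_idx <- anchor
  }
  belief
}

#' Variational free energy of the current step
#'
#' `F = E_Q[log Q - log P]` over the current step's factors (transition
#' prior, observation likelihood and, in normal mode, position likelihood).
#' F is bounded below by the negative log evidence of the observation, with
#' equality exactly when `Q` is the step's exact posterior.
#'
#' @param belief the belief whose `q` is evaluated (need not be the exact
#'   posterior).
#' @param model a `cognav_model`.
#' @param action,obs as in [update_belief()].
#' @param q_prev the posterior of the previous step (defaults to uniform).
#' @return scalar free energy in nats.
#' @export
compute_vfe <- function(belief, model, action, obs, q_prev = NULL) {
  S <- n_states(model)
  if (is.null(q_prev)) q_prev <- rep(1 / S, S)
  prior <- if (is.null(action)) rep(1 / S, S) else
    as.vector(trans_likelihood(model, action) %*% q_prev)
  cid <- match(obs$color_name, model$colors)
  joint <- prior * obs_likelihood(model)[cid, ]
  if (belief$mode == "normal")
    joint <- joint * pose_factor(model, belief$pose_idx)
  q <- belief$q
  keep <- q > 0
  sum(q[keep] * (log(q[keep]) - log(joint[keep])))
}
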