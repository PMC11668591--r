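#' The agent's generative model
#'
#' A `cognav_model` is a parameter store of Dirichlet counts:
#' * `A_o` (observation x state): observation likelihood P(o|s);
#' * `A_p` (position x state): position likelihood P(p|s);
#' * `B_s` (next-state x state x action): state transitions P(s'|s,a);
#' plus the deterministic position-transition map `B_p` (position x action,
#' giving the successor position index, `NA` = unknown, `-1` = believed
#' blocked), the pose table, the pose/state bindings, and a border-cell
#' memory `walls` (state x direction, `NA` = never observed).
#'
#' All counts are at least `epsilon`, so every conditional slice normalizes
#' to a proper categorical.  Growth operations append cells at `epsilon` and
#' never change existing counts.
#'
#' @param first_color color name of the very first observation.
#' @param config a [cognav_config()].
#' @return a `cognav_model` with one state, one observation and the origin
#'   pose (0,0) bound to state 1.
#' @export
new_model <- function(first_color, config = cognav_config()) {
  eps <- config$epsilon
  m <- structure(list(
    config = config,
    colors = first_color,
    A_o = matrix(eps, 1, 1, dimnames = list(first_color, NULL)),
    poses = matrix(0L, 1, 2, dimnames = list(NULL, c("u", "v"))),
    A_p = matrix(eps, 1, 1),
    B_s = array(eps, c(1, 1, 5), dimnames = list(NULL, NULL, ACTIONS)),
    B_p = matrix(NA_integer_, 1, 5, dimnames = list(NULL, ACTIONS)),
    state_pose = NA_integer_,
    pose_state = NA_integer_,
    walls = matrix(NA, 1, 4, dimnames = list(NULL, c("N", "E", "S", "W")))
  ), class = "cognav_model")
  m$B_p[1, "Stay"] <- 1L
  m <- bind_pose_to_state(m, 1L, 1L)
  m$A_o[first_color, 1] <- m$A_o[first_color, 1] + config$eta_exp
  m
}

#' @export
print.cognav_model <- function(x, ...) {
  cat(sprintf("cognav_model: %d states, %d observations, %d positions\n",
              n_states(x), n_obs(x), n_poses(x)))
  invisible(x)
}

#' Model dimensions
#' @param model a `cognav_model`.
#' @export
n_states <- function(model) ncol(model$A_o)
#' @rdname n_states
#' @export
n_obs <- function(model) nrow(model$A_o)
#' @rdname n_states
#' @export
n_poses <- function(model) nrow(model$poses)

#' Dirichlet mean of a conditional count slice
#'
#' @param counts nonnegative vector or matrix of pseudo-counts.
#' @return for a vector, the categorical `counts / sum(counts)`; for a
#'   matrix, each *column* normalized to sum to 1.
#' @export
normalize <- function(counts) {
  if (is.matrix(counts)) return(sweep(counts, 2, colSums(counts), "/"))
  counts / sum(counts)
}

# P(o|s) as an O x S column-stochastic matrix
obs_likelihood <- function(model) normalize(model$A_o)
# P(p|s) as a P x S column-stochastic matrix
pos_likelihood <- function(model) normalize(model$A_p)
# P(s'|s,a) for one action as an S x S column-stochastic matrix.  Stay is
# deterministic (the agent cannot change room by staying), mirroring the
# deterministic position map B_p.
trans_likelihood <- function(model, action) {
  S <- n_states(model)
  if (action == "Stay") return(diag(S))
  normalize(matrix(model$B_s[, , action], S, S))
}

#' Grow the state dimension by one
#'
#' All probability matrices gain a state slice at the base pseudo-count, so
#' the new state has uniform observation and transition distributions;
#' existing counts are untouched.
#'
#' @param model a `cognav_model`.
#' @return the model with `n_states(model) + 1` states.
#' @export
grow_state <- function(model) {
  eps <- model$config$epsilon
  S <- n_states(model)
  model$A_o <- cbind(model$A_o, eps)
  dimnames(model$A_o) <- list(model$colors, NULL)
  model$A_p <- cbind(model$A_p, eps)
  dimnames(model$A_p) <- NULL
  B <- array(eps, c(S + 1L, S + 1L, 5L), dimnames = list(NULL, NULL, ACTIONS))
  B[seq_len(S), seq_len(S), ] <- model$B_s
  model$B_s <- B
  model$state_pose <- c(model$state_pose, NA_integer_)
  model$walls <- rbind(model$walls, NA)
  model
}

#' Grow the observation or position support
#'
#' @param model a `cognav_model`.
#' @param what `"observation"` or `"position"`.
#' @param color new color name (for observations).
#' @param pose integer `c(u, v)` internal pose (for positions).
#' @param from,action optional: the known pose index and direction this new
#'   position was reached/predicted from; records the deterministic
#'   `B_p` transition in both directions.
#' @return the grown model.  Re-adding a known color or pose is an error:
#'   callers check membership first.
#' @export
grow_support <- function(model, what = c("observation", "position"),
                         color = NULL, pose = NULL, from = NULL, action = NULL) {
  what <- match.arg(what)
  eps <- model$config$epsilon
  if (what == "observation") {
    if (color %in% model$colors) stop("color already in support: ", color)
    model$colors <- c(model$colors, color)
    model$A_o <- rbind(model$A_o, eps)
    dimnames(model$A_o) <- list(model$colors, NULL)
  } else {
    if (!is.na(pose_index(model, pose))) stop("pose already in support")
    model$poses <- rbind(model$poses, as.integer(pose))
    dimnames(model$poses) <- list(NULL, c("u", "v"))
    model$A_p <- rbind(model$A_p, eps)
    dimnames(model$A_p) <- NULL
    p <- nrow(model$poses)
    model$B_p <- rbind(model$B_p, NA_integer_)
    dimnames(model$B_p) <- list(NULL, ACTIONS)
    model$B_p[p, "Stay"] <- p
    model$pose_state <- c(model$pose_state, NA_integer_)
    if (!is.null(from)) {
      model$B_p[from, action] <- p
      model$B_p[p, opposite_action(action)] <- from
    }
  }
  model
}

#' Index of an internal pose, or `NA` if not yet in the support
#' @param model a `cognav_model`.
#' @param pose integer `c(u, v)`.
#' @export
pose_index <- function(model, pose) {
  hit <- which(model$poses[, 1] == pose[1] & model$poses[, 2] == pose[2])
  if (length(hit)) hit[1] else NA_integer_
}

#' Bind a pose to a state in the position likelihood
#'
#' Sets the `A_p` count at (pose, state) to the binding pseudo-count so that
#' P(state | pose) is effectively one-hot.  The binding is injective: a pose
#' already bound to a different state, or a state already bound to a
#' different pose, signals a bookkeeping bug and is an error.
#'
#' @param model a `cognav_model`.
#' @param pose_idx pose index.
#' @param state state index.
#' @export
bind_pose_to_state <- function(model, pose_idx, state) {
  ps <- model$pose_state[pose_idx]
  if (!is.na(ps) && ps != state)
    stop("pose already bound to a different state")
  sp <- model$state_pose[state]
  if (!is.na(sp) && sp != pose_idx)
    stop("state already bound to a different pose")
  model$A_p[pose_idx, state] <- model$config$kappa_bind
  model$pose_state[pose_idx] <- state
  model$state_pose[state] <- pose_idx
  model
}

#' State bound to a pose
#' @param model a `cognav_model`.
#' @param pose_idx pose index.
#' @return state index, or an error if the pose is unbound.
#' @export
state_at_pose <- function(model, pose_idx) {
  s <- model$pose_state[pose_idx]
  if (is.na(s)) stop("pose is not bound to any state")
  s
}
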