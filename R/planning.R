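#' Log-preference over observations
#'
#' The preference distribution is a softmax over the observation alphabet
#' with logit `utility_weight` on the preferred color and 0 elsewhere,
#' shifted so that a uniform preference scores exactly zero: utility then
#' vanishes identically during pure exploration, whatever the policy
#' length.
#'
#' @param model a `cognav_model`.
#' @param config a [cognav_config()].
#' @return numeric vector over the observation support.
#' @export
preference_logp <- function(model, config = model$config) {
  O <- n_obs(model)
  w <- config$utility_weight
  tgt <- if (is.null(config$pref_color)) NA_integer_ else
    match(config$pref_color, model$colors)
  if (w == 0 || is.na(tgt)) return(rep(0, O))
  logits <- rep(0, O)
  logits[tgt] <- w
  logits - log(sum(exp(logits))) + log(O)
}

# Directed graph of confident transitions under argmax dynamics: an edge
# s --a--> s' exists when s' is the argmax successor, differs from s, and its
# count shows at least one imagined update above the base pseudo-count (so
# pure-epsilon noise never creates an edge).
argmax_graph <- function(model) {
  S <- n_states(model)
  eps <- model$config$epsilon
  floor <- eps + model$config$eta_im / 2 - 1e-9
  succ <- array(NA_integer_, c(S, 4L), dimnames = list(NULL, c("N", "E", "S", "W")))
  for (a in c("N", "E", "S", "W")) {
    B <- matrix(model$B_s[, , a], S, S)
    for (s in seq_len(S)) {
      cnt <- B[, s]
      s2 <- which.max(cnt)
      if (s2 != s && cnt[s2] >= floor) succ[s, a] <- s2
    }
  }
  succ
}

#' Enumerate candidate policies
#'
#' One candidate per state reachable within the horizon: the shortest action
#' sequence to it under argmax `B_s`/`B_p` dynamics from the most likely
#' current state, plus the Stay policy.  This shortest-path-to-target
#' construction keeps 14-step horizons tractable (no exponential
#' enumeration).
#'
#' @param belief a `cognav_belief`.
#' @param model a `cognav_model`.
#' @param H planning horizon (>= 1).
#' @return list of policies, each `list(actions, target)`.
#' @export
enumerate_policies <- function(belief, model, H = model$config$horizon) {
  stopifnot(H >= 1)
  succ <- argmax_graph(model)
  s0 <- which.max(belief$q)
  S <- n_states(model)
  dist <- rep(NA_integer_, S); dist[s0] <- 0L
  par_state <- rep(NA_integer_, S); par_act <- rep(NA_character_, S)
  frontier <- s0
  while (length(frontier)) {
    nxt <- integer(0)
    for (s in frontier) {
      if (dist[s] >= H) next
      for (a in c("N", "E", "S", "W")) {
        s2 <- succ[s, a]
        if (!is.na(s2) && is.na(dist[s2])) {
          dist[s2] <- dist[s] + 1L
          par_state[s2] <- s; par_act[s2] <- a
          nxt <- c(nxt, s2)
        }
      }
    }
    frontier <- nxt
  }
  pols <- list(list(actions = "Stay", target = s0))
  for (s in which(!is.na(dist) & dist > 0L)) {
    acts <- character(dist[s]); cur <- s
    for (k in dist[s]:1) { acts[k] <- par_act[cur]; cur <- par_state[cur] }
    pols[[length(pols) + 1L]] <- list(actions = acts, target = s)
  }
  pols
}

# Pre-computed quantities shared by all EFE evaluations of one planning step.
plan_context <- function(model, config = model$config) {
  S <- n_states(model)
  O <- n_obs(model)
  ao_tot <- colSums(model$A_o)
  W_o <- 0.5 * (1 / model$A_o - matrix(1 / ao_tot, O, S, byrow = TRUE))
  # predictive observation likelihood: evidence counts only; states without
  # observation experience (imagined) predict uniformly
  E <- pmax(model$A_o - config$epsilon, 0)
  et <- colSums(E)
  A <- sweep(E, 2, pmax(et, 1e-12), "/")
  A[, et <= 1e-12] <- 1 / O
  Tm <- list(); W_B <- list()
  eps <- config$epsilon
  for (a in c("N", "E", "S", "W")) {
    B <- matrix(model$B_s[, , a], S, S)
    tot <- colSums(B)
    W_B[[a]] <- 0.5 * (1 / B - matrix(1 / tot, S, S, byrow = TRUE))
    # rollout dynamics: evidence counts only — the eps prior stays in the
    # learning and map statistics but would diffuse multi-step predictions
    E <- pmax(B - eps, 0)
    et <- colSums(E)
    Tm[[a]] <- sweep(E, 2, pmax(et, 1e-12), "/")
    none <- et <= 1e-12           # no evidence for this action: predict stay
    if (any(none)) Tm[[a]][cbind(which(none), which(none))] <- 1
  }
  Tm[["Stay"]] <- diag(S)
  wall <- model$walls
  wall[is.na(wall)] <- FALSE
  list(A = A, W_o = W_o, Tm = Tm, W_B = W_B, wall = wall,
       pref = preference_logp(model, config), S = S, config = config)
}

#' Expected free energy of a policy
#'
#' The belief is rolled forward through the transition model for each action
#' of the policy (padded with Stay to the horizon, so candidates of
#' different path lengths are compared over the same number of predicted
#' steps).  Per predicted step the record accumulates:
#' * `info_gain_state`: the expected KL between posterior and prior state
#'   beliefs under predicted observations (the mutual information between
#'   predicted state and observation) — salient wherever the predicted
#'   observation would disambiguate states;
#' * `info_gain_params`: Dirichlet novelty of the observation and transition
#'   counts the step would update, computed from the standard half-inverse
#'   count difference, which makes never-observed (imagined) states and
#'   unconfirmed doors attractive;
#' * `utility`: expected log-preference of the predicted observation;
#' * `collision_risk`: the probability of stepping into a remembered wall,
#'   with P(collision) binary per state (the risk term).
#' `total` is the summed expected free energy `G`; smaller is better.
#'
#' @param policy `list(actions, target)` from [enumerate_policies()].
#' @param belief a `cognav_belief`.
#' @param model a `cognav_model`.
#' @param config a [cognav_config()].
#' @param ctx optional precomputed context (internal).
#' @return list of class `efe_record`.
#' @export
expected_free_energy <- function(policy, belief, model,
                                 config = model$config, ctx = NULL) {
  if (is.null(ctx)) ctx <- plan_context(model, config)
  H <- config$horizon
  acts <- policy$actions
  if (length(acts) < H) acts <- c(acts, rep("Stay", H - length(acts)))
  q <- belief$q
  ig_state <- ig_par <- util <- risk <- 0
  for (a in acts) {
    if (a != "Stay") risk <- risk + sum(q * ctx$wall[, a])
    qn <- as.vector(ctx$Tm[[a]] %*% q)
    if (a != "Stay")
      ig_par <- ig_par + sum(q * colSums(ctx$W_B[[a]] * ctx$Tm[[a]]))
    J <- ctx$A * rep(qn, each = nrow(ctx$A))    # J[o,s] = P(o|s) q(s)
    po <- rowSums(J)
    pos <- which(J > 0)
    # KL written as E_J[log P(o|s) - log P(o)]: both factors are bounded
    # away from zero wherever J > 0, unlike the raw joint
    lr <- log(ctx$A) - matrix(log(po), nrow(ctx$A), ctx$S)
    ig_state <- ig_state + sum(J[pos] * lr[pos])
    ig_par <- ig_par + sum(J * ctx$W_o)
    util <- util + sum(po * ctx$pref)
    q <- qn
  }
  total <- -(ig_state + ig_par) - util + config$collision_penalty * risk
  structure(list(info_gain_state = ig_state, info_gain_params = ig_par,
                 utility = util, collision_risk = risk, total = total),
            class = "efe_record")
}

#' Softmax policy selection
#'
#' Samples a policy from `sigma(-gamma * G)`; only its first action is
#' executed (the agent re-plans every step).
#'
#' @param policies list of policies.
#' @param G numeric vector of their total expected free energies.
#' @param gamma softmax temperature.
#' @return list with `index`, `policy`, `action` (the first action) and
#'   `probs` (the full selection distribution).
#' @export
select_action <- function(policies, G, gamma) {
  stopifnot(length(policies) >= 1, length(G) == length(policies))
  z <- -gamma * (G - min(G))
  p <- exp(z) / sum(exp(z))
  i <- sample.int(length(p), 1L, prob = p)
  list(index = i, policy = policies[[i]], action = policies[[i]]$actions[1],
       probs = p)
}
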