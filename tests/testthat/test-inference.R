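test_that("posterior matches hand Bayes on the two-state toy", {
  m <- toy_two_state(0.9)
  b <- new_belief(m)
  b$q <- c(0.5, 0.5)
  b$mode <- "lost"                      # observation-only: no position factor
  obs <- list(color_name = "o1", moved = FALSE)
  # uniform prior, uniform transitions, P(o1|s) = (.9, .1) => q = (.9, .1)
  b2 <- update_belief(b, m, "Stay", obs)
  expect_equal(b2$q, c(0.9, 0.1), tolerance = 1e-12)
  expect_equal(b2$confidence, 0.9)
})

test_that("one observation localizes exactly in a distinct-color maze", {
  ep <- learned_model(corridor_1x3(), start = c(0, 0), seed = 9)
  m <- ep$model
  b <- new_belief(m)
  b$q <- rep(1 / n_states(m), n_states(m))
  b$mode <- "lost"
  obs <- observe_world(corridor_1x3(), c(1, 0))   # unique green room
  b2 <- update_belief(b, m, NULL, obs)
  expect_gte(b2$confidence, 0.9)
  s_hat <- which.max(b2$q)
  expect_equal(m$colors[which.max(m$A_o[, s_hat])], "green")
})

test_that("the aliased T-maze start color splits the posterior three ways", {
  lay <- maze_fixture("T_maze_alias")
  ep <- learned_model(lay, start = c(4, 3), seed = 7)
  m <- ep$model
  b <- new_belief(m)
  b$q <- rep(1 / n_states(m), n_states(m))
  b$mode <- "lost"
  obs <- observe_world(lay, c(2, 0))              # gray, visible in 3 rooms
  b2 <- update_belief(b, m, NULL, obs)
  top3 <- sort(b2$q, decreasing = TRUE)[1:3]
  expect_gte(sum(top3), 0.9)                      # mass concentrated on 3 states
  expect_lt(b2$confidence, 0.5)                   # but divided between them
  expect_gt(min(top3) / max(top3), 0.3)
})

test_that("free energy equals negative log evidence exactly at the posterior, and exceeds it elsewhere", {
  m <- toy_two_state(0.9)
  obs <- list(color_name = "o1", moved = FALSE)
  exact <- new_belief(m); exact$mode <- "lost"
  exact$q <- c(0.9, 0.1)
  # evidence under uniform prior: 0.5*0.9 + 0.5*0.1 = 0.5
  f_exact <- compute_vfe(exact, m, "Stay", obs, q_prev = c(0.5, 0.5))
  expect_equal(f_exact, -log(0.5), tolerance = 1e-12)
  worse <- exact
  worse$q <- c(0.6, 0.4)
  f_worse <- compute_vfe(worse, m, "Stay", obs, q_prev = c(0.5, 0.5))
  expect_gt(f_worse, f_exact)
  # KL identity: F = -log evidence + KL(q || posterior)
  kl <- sum(worse$q * log(worse$q / exact$q))
  expect_equal(f_worse, -log(0.5) + kl, tolerance = 1e-12)
})

test_that("confidence gating has hysteresis and re-anchors the pose on recovery", {
  m <- new_model("red", cognav_config())
  m <- grow_support(m, "position", pose = c(1, 0), from = 1L, action = "E")
  m <- grow_state(m)
  m <- bind_pose_to_state(m, 2L, 2L)
  b <- new_belief(m); b <- sync_belief(b, m)
  b$q <- c(0.9, 0.1); b$confidence <- 0.9
  expect_equal(check_confidence(b, m)$mode, "normal")
  b$q <- c(0.55, 0.45); b$confidence <- 0.45
  b2 <- check_confidence(b, m)
  expect_equal(b2$mode, "lost")               # dropped below the 0.5 threshold
  b2$q <- c(0.4, 0.6); b2$confidence <- 0.6
  expect_equal(check_confidence(b2, m)$mode, "lost")   # below recovery: still lost
  b2$q <- c(0.1, 0.9); b2$confidence <- 0.9
  b3 <- check_confidence(b2, m)
  expect_equal(b3$mode, "normal")
  expect_equal(b3$pose_idx, 2L)               # re-anchored to state 2's pose
})

test_that("a kidnapped agent loses confidence, freezes learning, and re-localizes within four observations", {
  lay <- maze_fixture("T_maze_alias")
  ep <- learned_model(lay, start = c(4, 3), seed = 7)
  model <- ep$model
  # place the agent's belief at the west arm end, then kidnap to the stem
  csr <- room_state_map(model, lay, c(4, 3))
  s_arm <- csr[["0,3"]]
  belief <- new_belief(model); belief <- sync_belief(belief, model)
  belief$q[] <- 0; belief$q[s_arm] <- 1
  belief$confidence <- 1
  belief$pose_idx <- model$state_pose[s_arm]
  run <- start_run(lay, start = c(2, 0), config = cognav_config(),
                   model = model, belief = belief)
  expect_lt(run$belief$confidence, 0.5)       # contradictory gray observation
  expect_equal(run$belief$mode, "lost")
  counts_frozen <- run$model$B_s
  steps_to_recover <- NA_integer_
  for (i in 1:4) {
    if (run$belief$mode == "lost")
      expect_identical(run$model$B_s, counts_frozen)  # no learning while lost
    run_step(run)
    if (is.na(steps_to_recover) && run$belief$confidence > 0.99)
      steps_to_recover <- i
  }
  expect_lte(steps_to_recover, 4L)
  expect_equal(run$belief$mode, "normal")
  # the recovered state is the one truly underfoot
  s_hat <- which.max(run$belief$q)
  truth <- room_state_map(run$model, lay, c(4, 3))
  expect_equal(s_hat, unname(truth[paste0(run$pose[1], ",", run$pose[2])]))
})
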