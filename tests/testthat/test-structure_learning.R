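test_that("imagining the frontier grows states over open doors and self-loops over walls", {
  cfg <- cognav_config()
  lay <- corridor_1x3()
  m <- new_model("red", cfg)
  b <- new_belief(m)
  obs <- observe_world(lay, c(0, 0))   # door E, walls N/S/W
  m2 <- imagine_frontier(m, b, obs)
  expect_equal(n_states(m2), 2L)                       # one new state behind E
  expect_equal(n_poses(m2), 2L)
  expect_equal(state_at_pose(m2, 2L), 2L)              # pose bound on creation
  expect_equal(unname(normalize(m2$A_o[, 2])), 1)      # uniform (single color so far)
  expect_equal(unname(m2$B_s[1, 1, "N"]), cfg$epsilon + cfg$eta_im)  # wall self-loop
  expect_equal(unname(m2$B_s[2, 1, "E"]), cfg$epsilon + cfg$eta_im)
  expect_equal(unname(m2$B_s[1, 2, "W"]), cfg$epsilon + cfg$eta_im / 2)  # weak reverse
  expect_equal(unname(m2$B_p[1, "N"]), -1L)                    # blocked position edge
  # idempotent: a second imagination links to the existing state, no growth
  m3 <- imagine_frontier(m2, sync_belief(b, m2), obs)
  expect_equal(n_states(m3), 2L)
  expect_equal(n_poses(m3), 2L)
  expect_equal(unname(m3$B_s[2, 1, "E"]), cfg$epsilon + 2 * cfg$eta_im)
})

test_that("one experienced crossing outweighs its imagined precursor", {
  cfg <- cognav_config()
  m <- new_model("red", cfg)
  b <- new_belief(m)
  m <- imagine_frontier(m, b, observe_world(corridor_1x3(), c(0, 0)))
  p_im <- trans_likelihood(m, "E")[2, 1]
  m2 <- learn_from_transition(m, 1L, "E", 2L, "red")
  p_exp <- trans_likelihood(m2, "E")[2, 1]
  expect_gt(p_exp, p_im)
  # closed form: counts (eps + eta_im + eta_exp) / column total
  cnt <- cfg$epsilon + cfg$eta_im + cfg$eta_exp
  expect_equal(unname(m2$B_s[2, 1, "E"]), cnt)
  expect_equal(p_exp, cnt / sum(m2$B_s[, 1, "E"]))
  # bi-directional: the reverse transition was reinforced too
  expect_equal(unname(m2$B_s[1, 2, "W"]),
               cfg$epsilon + cfg$eta_im / 2 + cfg$eta_exp)
  # repetition is monotone
  m3 <- learn_from_transition(m2, 1L, "E", 2L, "red")
  expect_gt(trans_likelihood(m3, "E")[2, 1], p_exp)
})

test_that("a real link beats an imagined link from the same state", {
  cfg <- cognav_config(eta_exp = 1, eta_im = 0.2)
  m <- new_model("red", cfg)
  b <- new_belief(m)
  # two open doors imagined (E and N)
  obs <- observe_world(corridor_1x3(), c(0, 0))
  obs$collisions[["N"]] <- FALSE
  m <- imagine_frontier(m, b, obs)
  expect_equal(n_states(m), 3L)
  m <- learn_from_transition(m, 1L, "E", 2L, "red")   # only E experienced
  expect_gt(trans_likelihood(m, "E")[2, 1], trans_likelihood(m, "N")[3, 1])
})

test_that("negative learning floors at epsilon, flips the successor, and is reversible", {
  cfg <- cognav_config()
  m <- new_model("red", cfg)
  b <- new_belief(m)
  m <- imagine_frontier(m, b, observe_world(corridor_1x3(), c(0, 0)))
  for (i in 1:5) m <- learn_from_transition(m, 1L, "E", 2L, "red")
  expect_equal(which.max(m$B_s[, 1, "E"]), 2L)
  m2 <- negative_update(m, 1L, "E", confidence = 1)
  expect_gte(min(m2$B_s), cfg$epsilon)                 # floor holds
  expect_false(believed_open(m2, 1L, "E"))             # one contradiction at certainty
  expect_equal(unname(m2$B_p[1, "E"]), -1L)
  expect_true(isTRUE(m2$walls[1, "E"]))
  # under partial confidence the evidence decays geometrically instead
  m3 <- negative_update(m, 1L, "E", confidence = 0.4)
  expect_true(believed_open(m3, 1L, "E"))
  expect_lt(m3$B_s[2, 1, "E"], m$B_s[2, 1, "E"])
  for (i in 1:10) m3 <- negative_update(m3, 1L, "E", 0.4)
  expect_false(believed_open(m3, 1L, "E"))
  # plasticity: re-experiencing the door restores the belief
  m4 <- imagine_frontier(m2, sync_belief(b, m2), observe_world(corridor_1x3(), c(0, 0)))
  m4 <- learn_from_transition(m4, 1L, "E", 2L, "red")
  expect_equal(which.max(m4$B_s[, 1, "E"]), 2L)
  expect_true(believed_open(m4, 1L, "E"))
})

test_that("expansion precedes experience: every visited room's open doors have successor states", {
  lay <- maze_fixture("3x3")
  cfg <- cognav_config()
  set.seed(21)
  run <- start_run(lay, start = c(0, 1), config = cfg)
  for (i in 1:12) {
    run_step(run)
    if (run$belief$mode != "normal") next
    s <- which.max(run$belief$q)
    p <- run$model$state_pose[s]
    if (is.na(p) || p != run$belief$pose_idx) next
    x <- run$pose[1]; y <- run$pose[2]
    for (d in c("N", "E", "S", "W")) {
      if (!cognav:::has_door(lay, x, y, d)) next
      nxt <- run$model$B_p[p, d]
      expect_false(is.na(nxt))
      expect_gt(nxt, 0)
      expect_false(is.na(run$model$pose_state[nxt]))   # a state lives behind it
    }
  }
  # dimensions are monotone over the episode
  lg <- run_log(run)
  expect_true(all(diff(lg$n_states) >= 0))
  expect_true(all(diff(lg$n_obs) >= 0))
  expect_true(all(diff(lg$n_poses) >= 0))
})

test_that("map confidence scores against ground truth and flags coverage deficits", {
  lay <- two_rooms()
  cfg <- cognav_config()
  m <- new_model("red", cfg)
  b <- new_belief(m)
  m <- imagine_frontier(m, b, observe_world(lay, c(0, 0)))
  # all-epsilon / imagined-only model fails
  csr <- room_state_map(m, lay, c(0, 0))
  expect_false(map_confidence(m, lay, csr)$pass)
  expect_true("1,0" %in% map_confidence(m, lay, csr)$coverage_deficit)
  # strong experienced counts pass with confidence near 1
  m <- grow_support(m, "observation", color = "blue")
  for (i in 1:20) m <- learn_from_transition(m, 1L, "E", 2L, "blue")
  csr2 <- room_state_map(m, lay, c(0, 0))
  mc <- map_confidence(m, lay, csr2)
  expect_true(mc$pass)
  expect_gt(mc$confidence, 0.9)
})

test_that("exploration terminates exactly at the first map-confidence pass", {
  lay <- maze_fixture("3x3")
  ep <- learned_model(lay, start = c(0, 1), seed = 31)
  mc_final <- map_confidence(ep$model, lay, room_state_map(ep$model, lay, c(0, 1)))
  expect_true(mc_final$pass)
  expect_equal(ep$reason, "map-learned")
  expect_gte(ep$steps, min_coverage_steps(lay, c(0, 1)))
})
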