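test_that("policy candidates cover reachable targets within the horizon, plus Stay", {
  cfg <- cognav_config()
  lay <- corridor_1x3()
  m <- new_model("red", cfg)
  b <- new_belief(m)
  m <- imagine_frontier(m, b, observe_world(lay, c(0, 0)))
  b <- sync_belief(b, m)
  pols <- enumerate_policies(b, m, H = 6)
  expect_gte(length(pols), 2L)                       # Stay + the imagined frontier
  expect_true(any(vapply(pols, function(p) identical(p$actions, "Stay"), TRUE)))
  expect_true(any(vapply(pols, function(p) identical(p$actions, "E"), TRUE)))
  # a target beyond the horizon is excluded
  ep <- learned_model(maze_fixture("Donuts"), start = c(0, 0), seed = 13)
  b2 <- new_belief(ep$model); b2 <- sync_belief(b2, ep$model)
  b2$q[] <- 0
  csr <- room_state_map(ep$model, maze_fixture("Donuts"), c(0, 0))
  b2$q[csr[["0,0"]]] <- 1
  far <- csr[["3,3"]]                                # 6 doors away on the ring
  p3 <- enumerate_policies(b2, ep$model, H = 3)
  expect_false(far %in% vapply(p3, `[[`, 0L, "target"))
  p8 <- enumerate_policies(b2, ep$model, H = 8)
  expect_true(far %in% vapply(p8, `[[`, 0L, "target"))
  expect_true(all(vapply(p8, function(p) length(p$actions) <= 8, TRUE)))
})

test_that("information-gain terms are nonnegative for every policy", {
  ep <- learned_model(maze_fixture("3x3"), start = c(0, 1), seed = 17)
  m <- ep$model; b <- ep$belief
  ctx <- cognav:::plan_context(m, m$config)
  for (p in enumerate_policies(b, m, 14)) {
    r <- expected_free_energy(p, b, m, m$config, ctx)
    expect_gte(r$info_gain_state, -1e-12)
    expect_gte(r$info_gain_params, -1e-12)
    expect_gte(r$collision_risk, 0)
  }
})

test_that("with a uniform preference, utility is identical across policies", {
  cfg <- cognav_config(utility_weight = 0)
  ep <- learned_model(maze_fixture("3x3"), start = c(0, 1), seed = 17, config = cfg)
  m <- ep$model; b <- ep$belief
  ctx <- cognav:::plan_context(m, cfg)
  utils <- vapply(enumerate_policies(b, m, 8), function(p)
    expected_free_energy(p, b, m, cfg, ctx)$utility, 0)
  expect_equal(max(utils) - min(utils), 0)
})

test_that("a policy ending at an imagined state carries more expected gain than one ending at a learned state", {
  cfg <- cognav_config()
  lay <- corridor_1x3()
  m <- new_model("red", cfg)
  b <- new_belief(m)
  m <- imagine_frontier(m, b, observe_world(lay, c(0, 0)))
  b <- sync_belief(b, m)
  ctx <- cognav:::plan_context(m, cfg)
  g_frontier <- expected_free_energy(list(actions = "E", target = 2L), b, m, cfg, ctx)
  g_stay <- expected_free_energy(list(actions = "Stay", target = 1L), b, m, cfg, ctx)
  expect_gt(g_frontier$info_gain_params, g_stay$info_gain_params)
  expect_lt(g_frontier$total, g_stay$total)
})

test_that("planning into a remembered wall incurs collision risk and no fictitious progress", {
  cfg <- cognav_config()
  m <- new_model("red", cfg)
  b <- new_belief(m)
  m <- imagine_frontier(m, b, observe_world(corridor_1x3(), c(0, 0)))
  b <- sync_belief(b, m)
  ctx <- cognav:::plan_context(m, cfg)
  g_wall <- expected_free_energy(list(actions = "N", target = 1L), b, m, cfg, ctx)
  expect_gt(g_wall$collision_risk, 0)
  # the rollout stays at the same state: no observation change is predicted
  expect_lt(g_wall$info_gain_state, 1e-6)
})

test_that("softmax selection is temperature-consistent", {
  pols <- list(list(actions = "N", target = 1L), list(actions = "E", target = 2L),
               list(actions = "S", target = 3L))
  G <- c(1.0, 0.2, 1.0)
  set.seed(1)
  sel <- select_action(pols, G, gamma = 1e6)
  expect_equal(sel$index, 2L)                         # gamma -> Inf: argmin G
  expect_equal(sum(sel$probs), 1)
  # equal-G candidates split evenly
  sel2 <- select_action(pols[1:2], c(0.7, 0.7), gamma = 8)
  expect_equal(sel2$probs, c(0.5, 0.5))
  # any G vector yields a proper distribution
  sel3 <- select_action(pols, c(-50, 0, 50), gamma = 0.3)
  expect_equal(sum(sel3$probs), 1)
  expect_true(all(sel3$probs >= 0))
})

test_that("on a fully learned 3x3 with a goal preference, the best policy is the true shortest path", {
  lay <- maze_fixture("3x3")
  cfg <- cognav_config(utility_weight = 2, pref_color = "lime")
  ep <- learned_model(lay, start = c(0, 1), seed = 19)
  m <- ep$model; m$config <- cfg
  b <- ep$belief
  ctx <- cognav:::plan_context(m, cfg)
  pols <- enumerate_policies(b, m, 14)
  G <- vapply(pols, function(p) expected_free_energy(p, b, m, cfg, ctx)$total, 0)
  best <- pols[[which.min(G)]]
  csr <- room_state_map(m, lay, c(0, 1))
  lime_room <- which(!lay$void & lay$color == match("lime", lay$color_names), arr.ind = TRUE)
  start_room <- c(run_log(ep$run)$x[nrow(ep$log)], run_log(ep$run)$y[nrow(ep$log)])
  oracle <- shortest_path_steps(lay, start_room, "lime")
  expect_equal(best$target, unname(csr[paste0(lime_room[1] - 1L, ",", lime_room[2] - 1L)]))
  expect_equal(length(best$actions), oracle)
})
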