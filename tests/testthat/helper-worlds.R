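# Tiny layouts built in code, plus model builders used across test files.

corridor_1x3 <- function() load_layout(c(
  "name: corridor", "width: 3", "height: 1",
  "colors:", "red green blue",
  "ew_doors:", "d d",
  "ns_doors:",
  "starts:", "0 0", "1 0"))

two_rooms <- function() load_layout(c(
  "name: pair", "width: 2", "height: 1",
  "colors:", "red blue",
  "ew_doors:", "d",
  "ns_doors:",
  "starts:", "0 0"))

single_room <- function() load_layout(c(
  "name: cell", "width: 1", "height: 1",
  "colors:", "red",
  "ew_doors:",
  "ns_doors:",
  "starts:", "0 0"))

# a 2-state toy model with a chosen observation likelihood, uniform
# transitions, for hand-computed Bayes checks
toy_two_state <- function(p = 0.9, config = cognav_config()) {
  m <- new_model("o1", config)
  m <- grow_support(m, "observation", color = "o2")
  m <- grow_state(m)
  scale <- 10
  m$A_o[, 1] <- c(p, 1 - p) * scale
  m$A_o[, 2] <- c(1 - p, p) * scale
  m
}

# run a full exploration of `layout` and return the learned model/belief
learned_model <- function(layout, start = NULL, seed = 11,
                          config = cognav_config(), budget = 400) {
  ep <- run_episode(layout, start = start, config = config,
                    termination = "map", budget = budget, seed = seed)
  stopifnot(ep$success)
  ep
}
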