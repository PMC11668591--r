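Package: cognav
Title: Active-Inference Navigation with a Dynamically Expanding Cognitive Map
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An active-inference agent that learns a cognitive map of
    room-structured mini-grid mazes while navigating them.  The agent infers
    its state and pose from aliased color observations, expands its
    generative model over predicted, still un-visited locations, plans by
    expected free energy, and re-maps when collisions contradict learned
    beliefs.  Includes the room-maze simulator (obstacles, kidnapping),
    exact coverage and shortest-path oracles, and the exploration, goal,
    Tolman-maze and remapping experiment protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
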