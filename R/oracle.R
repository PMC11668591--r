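#' Exact minimum coverage walk length
#'
#' The oracle lower bound on exploration: the minimum number of moves whose
#' walk, starting from `start`, visits every (non-void, non-sealed) room at
#' least once.  Computed exactly by breadth-first search over
#' (room, visited-set) states with the visited set encoded as a bitmask, so
#' it is limited to layouts with at most 20 rooms.
#'
#' @param layout a `room_layout`.
#' @param start integer `c(x, y)` start pose, 0-based; defaults to the
#'   layout's first recorded start.
#' @return integer number of door-crossing moves.
#' @export
min_coverage_steps <- function(layout, start = NULL) {
  if (is.null(start)) {
    if (!length(layout$starts)) stop("layout has no recorded start pose")
    start <- layout$starts[[1]]
  }
  rooms <- which(!layout$void, arr.ind = TRUE)
  # deliberately sealed rooms (no doors at all) cannot be visited and are
  # excluded from the coverage requirement
  doors <- apply(rooms, 1, function(rc) {
    any(vapply(c("N", "E", "S", "W"),
               function(a) has_door(layout, rc[1] - 1L, rc[2] - 1L, a), TRUE))
  })
  if (nrow(rooms) > 1L) rooms <- rooms[doors, , drop = FALSE]
  n <- nrow(rooms)
  if (n > 20L) stop("min_coverage_steps: exact search limited to <= 20 rooms")
  id <- matrix(NA_integer_, layout$width, layout$height)
  id[rooms] <- seq_len(n)
  s0 <- id[start[1] + 1L, start[2] + 1L]
  if (is.na(s0)) stop("start pose is not a room")
  if (n == 1L) return(0L)

  # successor list per room
  succ <- vector("list", n)
  for (i in seq_len(n)) {
    x <- rooms[i, 1] - 1L; y <- rooms[i, 2] - 1L
    nb <- integer(0)
    for (a in c("N", "E", "S", "W"))
      if (has_door(layout, x, y, a))
        nb <- c(nb, id[x + DX[[a]] + 1L, y + DY[[a]] + 1L])
    succ[[i]] <- nb
  }
  full <- bitwShiftL(1L, n) - 1L
  if (n == 31L) stop("bitmask overflow")  # unreachable given the 20-room cap

  # state code = mask * n + (room - 1)
  enc <- function(room, mask) mask * n + (room - 1L)
  seen <- new.env(hash = TRUE, size = 1024L)
  frontier_room <- s0
  frontier_mask <- bitwShiftL(1L, s0 - 1L)
  assign(as.character(enc(s0, frontier_mask)), TRUE, envir = seen)
  depth <- 0L
  repeat {
    if (any(frontier_mask == full)) return(depth)
    nr <- integer(0); nm <- integer(0)
    for (k in seq_along(frontier_room)) {
      r <- frontier_room[k]; m <- frontier_mask[k]
      for (r2 in succ[[r]]) {
        m2 <- bitwOr(m, bitwShiftL(1L, r2 - 1L))
        key <- as.character(enc(r2, m2))
        if (is.null(seen[[key]])) {
          assign(key, TRUE, envir = seen)
          nr <- c(nr, r2); nm <- c(nm, m2)
        }
      }
    }
    if (!length(nr)) stop("min_coverage_steps: layout not connected from start")
    frontier_room <- nr; frontier_mask <- nm
    depth <- depth + 1L
  }
}

#' Oracle coverage averaged over a layout's recorded start poses
#'
#' @param layout a `room_layout` with one or more `starts`.
#' @return list with `per_start` (one value per recorded start) and `mean`.
#' @export
oracle_coverage <- function(layout) {
  vals <- vapply(layout$starts, function(s) min_coverage_steps(layout, s), 1L)
  list(per_start = vals, mean = mean(vals))
}

#' Shortest door-path length to a goal room
#'
#' @param layout a `room_layout`.
#' @param start integer `c(x, y)`, 0-based.
#' @param goal either a pose `c(x, y)` or a color name/id: the nearest room
#'   satisfying it is used.
#' @return integer number of moves on the shortest path.
#' @export
shortest_path_steps <- function(layout, start, goal) {
  g <- layout_graph(layout)
  vn <- igraph::V(g)$name
  from <- paste0(start[1], ",", start[2])
  if (is.numeric(goal) && length(goal) == 2L) {
    to <- paste0(goal[1], ",", goal[2])
    if (!to %in% vn) stop("goal pose is not a room")
    targets <- to
  } else {
    cid <- if (is.character(goal)) match(goal, layout$color_names) else as.integer(goal)
    if (is.na(cid)) stop("unknown goal color")
    rooms <- which(!layout$void & layout$color == cid, arr.ind = TRUE)
    if (!nrow(rooms)) stop("no room satisfies the goal predicate")
    targets <- paste0(rooms[, 1] - 1L, ",", rooms[, 2] - 1L)
  }
  d <- igraph::distances(g, v = from, to = targets)
  if (all(is.infinite(d))) stop("goal unreachable from start")
  as.integer(min(d))
}
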