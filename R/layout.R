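# Actions are indexed 1..5 throughout the package.
ACTIONS <- c("N", "E", "S", "W", "Stay")
DX <- c(N = 0L, E = 1L, S = 0L, W = -1L, Stay = 0L)
DY <- c(N = 1L, E = 0L, S = -1L, W = 0L, Stay = 0L)
OPPOSITE <- c(N = "S", E = "W", S = "N", W = "E", Stay = "Stay")

#' Opposite cardinal direction
#'
#' @param action one of `"N"`, `"E"`, `"S"`, `"W"`, `"Stay"`.
#' @return the reverse direction; `"Stay"` maps to itself.
#' @export
opposite_action <- function(action) unname(OPPOSITE[action])

#' Room-maze layouts
#'
#' A `room_layout` is the ground-truth world: a `width` x `height` grid of
#' rooms, each with a floor color (the observation the agent receives) and a
#' door-or-wall flag on each of its four sides.  Cells may be void (not a
#' room, e.g. the hole of a donut-shaped maze); void cells are walled on all
#' sides and excluded from connectivity.  Coordinates are 0-based with x
#' increasing East and y increasing North.
#'
#' @param text a character scalar (or vector of lines) in the layout format
#'   described under [write_layout()].
#' @return an object of class `room_layout` with fields `width`, `height`,
#'   `color` (w x h integer matrix, `NA` for void), `color_names` (the color
#'   alphabet), `ew` ((w-1) x h logical matrix of doors between `(x,y)` and
#'   `(x+1,y)`), `ns` (w x (h-1) logical matrix of doors between `(x,y)` and
#'   `(x,y+1)`), `starts` (list of start poses) and `name`.
#' @details Shared sides are stored once, so the side-symmetry invariant
#'   (room `(x,y)` East flag equals room `(x+1,y)` West flag) holds by
#'   construction.  Grid-boundary sides and sides adjacent to a void cell
#'   are always walls.  The room graph must be connected over doors; a room
#'   with no doors at all is treated as deliberately sealed (the Donut
#'   blockage) and exempted, while disconnected multi-room components are
#'   rejected.
#' @export
load_layout <- function(text) {
  if (length(text) == 1L && grepl("\n", text)) text <- strsplit(text, "\n")[[1]]
  text <- sub("#.*$", "", text)
  text <- trimws(text, which = "right")
  text <- text[nzchar(trimws(text))]

  sections <- list()
  key <- NULL
  for (line in text) {
    if (grepl("^[A-Za-z_]+:", line)) {
      parts <- strsplit(line, ":", fixed = TRUE)[[1]]
      key <- trimws(parts[1])
      val <- trimws(paste(parts[-1], collapse = ":"))
      sections[[key]] <- if (nzchar(val)) val else character()
    } else {
      if (is.null(key)) stop("layout: content before any section header")
      sections[[key]] <- c(sections[[key]], trimws(line))
    }
  }
  need <- c("width", "height", "colors", "ew_doors", "ns_doors")
  miss <- setdiff(need, names(sections))
  if (length(miss)) stop("layout: missing section(s): ", paste(miss, collapse = ", "))

  w <- as.integer(sections$width)
  h <- as.integer(sections$height)
  if (is.na(w) || is.na(h) || w < 1L || h < 1L) stop("layout: bad dimensions")

  tok_grid <- function(lines, nrow_exp, ncol_exp, what) {
    if (length(lines) != nrow_exp)
      stop(sprintf("layout: %s expects %d rows, got %d", what, nrow_exp, length(lines)))
    rows <- lapply(lines, function(l) strsplit(l, "[[:space:]]+")[[1]])
    if (any(vapply(rows, length, 1L) != ncol_exp))
      stop(sprintf("layout: %s expects %d tokens per row", what, ncol_exp))
    do.call(rbind, rows)
  }

  # File rows run north (top) to south (bottom); internal y index 1 = south.
  ctok <- tok_grid(sections$colors, h, w, "colors")[h:1, , drop = FALSE]
  void <- t(ctok == ".")                       # w x h
  color_names <- sort(unique(as.vector(ctok[t(!void)])))
  color <- matrix(NA_integer_, w, h)
  color[!void] <- match(t(ctok)[!void], color_names)

  gate <- function(lines, nr, nc, what) {
    if (nr == 0L || nc == 0L) {
      if (length(lines)) stop(sprintf("layout: %s should be empty", what))
      return(matrix(logical(0), nc, nr))
    }
    g <- tok_grid(lines, nr, nc, what)[nr:1, , drop = FALSE]
    if (!all(g %in% c("d", "w"))) stop(sprintf("layout: %s tokens must be d|w", what))
    t(g == "d")
  }
  ew <- gate(sections$ew_doors, h, w - 1L, "ew_doors")        # (w-1) x h
  ns <- gate(sections$ns_doors, h - 1L, w, "ns_doors")        # w x (h-1)

  starts <- lapply(sections$starts %||% character(), function(l) {
    xy <- as.integer(strsplit(l, "[[:space:]]+")[[1]])
    if (length(xy) != 2L || anyNA(xy)) stop("layout: bad start pose")
    xy
  })

  layout <- structure(
    list(width = w, height = h, color = color, color_names = color_names,
         ew = ew, ns = ns, void = void, starts = starts,
         name = if (length(sections$name)) sections$name else "layout"),
    class = "room_layout")
  validate_layout(layout)
  layout
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname load_layout
#' @param layout a `room_layout`.
#' @return `write_layout` returns the layout document as a character vector of
#'   lines (invisibly writes nothing; pass to [writeLines()] to save).
#' @export
write_layout <- function(layout) {
  w <- layout$width; h <- layout$height
  ctok <- matrix(".", h, w)
  for (y in seq_len(h)) for (x in seq_len(w))
    if (!layout$void[x, y]) ctok[h - y + 1L, x] <- layout$color_names[layout$color[x, y]]
  gate_rows <- function(m, nr) {
    if (nr == 0L || nrow(m) == 0L) return(character())
    vapply(nr:1, function(y) paste(ifelse(m[, y], "d", "w"), collapse = " "), "")
  }
  c(paste0("name: ", layout$name),
    paste0("width: ", w), paste0("height: ", h),
    "colors:", apply(ctok, 1, paste, collapse = " "),
    "ew_doors:", gate_rows(layout$ew, h),
    "ns_doors:", if (h > 1L) vapply((h - 1L):1, function(y)
      paste(ifelse(layout$ns[, y], "d", "w"), collapse = " "), "") else character(),
    "starts:", vapply(layout$starts, function(s) paste(s, collapse = " "), ""))
}

validate_layout <- function(layout) {
  w <- layout$width; h <- layout$height
  # doors never border a void cell or leave the grid (boundary walls are implicit
  # in the storage scheme: there is no entry for them)
  if (w > 1L) for (x in seq_len(w - 1L)) for (y in seq_len(h))
    if (layout$ew[x, y] && (layout$void[x, y] || layout$void[x + 1L, y]))
      stop("layout: door on a side of a void cell at (", x - 1L, ",", y - 1L, ") East")
  if (h > 1L) for (x in seq_len(w)) for (y in seq_len(h - 1L))
    if (layout$ns[x, y] && (layout$void[x, y] || layout$void[x, y + 1L]))
      stop("layout: door on a side of a void cell at (", x - 1L, ",", y - 1L, ") North")
  for (s in layout$starts) {
    if (s[1] < 0L || s[1] >= w || s[2] < 0L || s[2] >= h || layout$void[s[1] + 1L, s[2] + 1L])
      stop("layout: start pose out of bounds or void")
  }
  g <- layout_graph(layout)
  rooms <- which(!layout$void)
  sealed <- attr(g, "sealed")
  core <- setdiff(seq_along(rooms), sealed)
  if (length(core) > 1L) {
    comp <- igraph::components(g)
    if (length(unique(comp$membership[core])) != 1L)
      stop("layout: rooms are not connected through doors")
  }
  invisible(layout)
}

# igraph over non-void rooms; vertex names "x,y" (0-based).  Rooms with no
# doors at all (deliberately sealed, e.g. the Donut blockage) are reported in
# attr "sealed" and tolerated by the connectivity check.
layout_graph <- function(layout) {
  w <- layout$width; h <- layout$height
  idx <- which(!layout$void, arr.ind = TRUE)
  vname <- paste0(idx[, 1] - 1L, ",", idx[, 2] - 1L)
  ed <- character(0)
  if (w > 1L) for (x in seq_len(w - 1L)) for (y in seq_len(h))
    if (isTRUE(layout$ew[x, y]))
      ed <- c(ed, paste0(x - 1L, ",", y - 1L), paste0(x, ",", y - 1L))
  if (h > 1L) for (x in seq_len(w)) for (y in seq_len(h - 1L))
    if (isTRUE(layout$ns[x, y]))
      ed <- c(ed, paste0(x - 1L, ",", y - 1L), paste0(x - 1L, ",", y))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(vname), name = vname)
  if (length(ed)) g <- igraph::add_edges(g, match(ed, vname))
  attr(g, "sealed") <- which(igraph::degree(g) == 0 & length(vname) > 1L)
  g
}

#' @export
print.room_layout <- function(x, ...) {
  cat(sprintf("room_layout '%s': %dx%d grid, %d rooms, %d colors, %d doors\n",
              x$name, x$width, x$height, sum(!x$void), length(x$color_names),
              sum(x$ew) + sum(x$ns)))
  invisible(x)
}

#' Number of (non-void) rooms in a layout
#' @param layout a `room_layout`.
#' @export
n_rooms <- function(layout) sum(!layout$void)

has_door <- function(layout, x, y, action) {
  # x, y 0-based; returns TRUE iff the side of room (x,y) in `action` is a door
  switch(action,
    N = y + 2L <= layout$height && layout$ns[x + 1L, y + 1L],
    S = y >= 1L && layout$ns[x + 1L, y],
    E = x + 2L <= layout$width && layout$ew[x + 1L, y + 1L],
    W = x >= 1L && layout$ew[x, y + 1L],
    Stay = FALSE)
}

#' Advance the world by one action
#'
#' Deterministic and total: a move through a door changes the pose; a move
#' into a wall (or `Stay`) leaves it unchanged.  The returned observation is
#' the floor color of the *resulting* room together with the collision flags
#' of its four sides (walls are only perceivable from the adjacent room).
#'
#' @param layout a `room_layout`.
#' @param pose integer `c(x, y)`, 0-based.
#' @param action one of `"N"`, `"E"`, `"S"`, `"W"`, `"Stay"`.
#' @return a list with `pose` (the new pose), and `obs`: a `step_result` with
#'   fields `color` (color id), `color_name`, `collisions` (named logical,
#'   TRUE where the side of the current room is a wall), `moved`.
#' @export
step_world <- function(layout, pose, action) {
  stopifnot(action %in% ACTIONS)
  x <- pose[1]; y <- pose[2]
  if (x < 0L || x >= layout$width || y < 0L || y >= layout$height)
    stop("pose out of bounds")
  moved <- action != "Stay" && has_door(layout, x, y, action)
  if (moved) { x <- x + DX[[action]]; y <- y + DY[[action]] }
  coll <- !vapply(c("N", "E", "S", "W"), function(d) has_door(layout, x, y, d), TRUE)
  obs <- structure(list(color = layout$color[x + 1L, y + 1L],
                        color_name = layout$color_names[layout$color[x + 1L, y + 1L]],
                        collisions = coll, moved = moved),
                   class = "step_result")
  list(pose = c(x, y), obs = obs)
}

#' Observe a room without acting
#'
#' Equivalent to [step_world()] with action `"Stay"`; used for the very first
#' perception of an episode.
#' @inheritParams step_world
#' @export
observe_world <- function(layout, pose) step_world(layout, pose, "Stay")$obs

#' Modify the world: obstacles and kidnapping
#'
#' `obstacle-add` turns an interior shared side into a wall (a Tolman-style
#' block), `obstacle-remove` re-opens it, `seal-room` walls off all four
#' sides of a room (the Donut "closed room"), and `kidnap` simply returns a
#' new pose: the agent is never signaled.
#'
#' @param layout a `room_layout`.
#' @param change `"obstacle-add"`, `"obstacle-remove"`, `"seal-room"` or
#'   `"kidnap"`.
#' @param at for obstacles, `list(pose, action)` naming the side of room
#'   `pose` in direction `action`; for `seal-room` and `kidnap`, a pose.
#' @return the modified `room_layout` (obstacles), or the new pose (kidnap).
#' @export
modify_world <- function(layout, change, at) {
  if (change == "kidnap") {
    p <- at
    if (p[1] < 0L || p[1] >= layout$width || p[2] < 0L || p[2] >= layout$height ||
        layout$void[p[1] + 1L, p[2] + 1L])
      stop("kidnap target out of bounds")
    return(as.integer(p))
  }
  if (change == "seal-room") {
    p <- at
    for (a in c("N", "E", "S", "W"))
      if (has_door(layout, p[1], p[2], a))
        layout <- set_gate(layout, p, a, FALSE)
    validate_layout(layout)
    return(layout)
  }
  stopifnot(change %in% c("obstacle-add", "obstacle-remove"))
  p <- at$pose; a <- at$action
  x <- p[1]; y <- p[2]
  interior <- switch(a,
    N = y + 2L <= layout$height, S = y >= 1L,
    E = x + 2L <= layout$width, W = x >= 1L, FALSE)
  if (!interior) stop("obstacle edit on a boundary side")
  layout <- set_gate(layout, p, a, change == "obstacle-remove")
  validate_layout(layout)
  layout
}

set_gate <- function(layout, pose, action, open) {
  x <- pose[1]; y <- pose[2]
  switch(action,
    N = { layout$ns[x + 1L, y + 1L] <- open },
    S = { layout$ns[x + 1L, y] <- open },
    E = { layout$ew[x + 1L, y + 1L] <- open },
    W = { layout$ew[x, y + 1L] <- open })
  layout
}

#' Packaged maze fixtures
#'
#' Loads one of the reconstructed mini-grid environments shipped with the
#' package: `3x3`, `3x3_alias`, `4x4`, `4x4_alias`, `T_maze`, `T_maze_alias`,
#' `Donuts`, `Tolman`, plus the obstacle variants `Tolman_A`, `Tolman_B` and
#' `Donuts_blocked`.
#'
#' @param name fixture name.
#' @return a `room_layout`.
#' @export
maze_fixture <- function(name) {
  path <- system.file("extdata", paste0(name, ".layout"), package = "cognav")
  if (!nzchar(path)) stop("unknown fixture: ", name)
  load_layout(readLines(path))
}

#' @rdname maze_fixture
#' @export
maze_fixture_names <- function() {
  sub("\\.layout$", "", dir(system.file("extdata", package = "cognav"),
                            pattern = "\\.layout$"))
}
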