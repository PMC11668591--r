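#' Model snapshot export / import
#'
#' Serializes a `cognav_model` (dimensions, count tensors, pose table,
#' bindings, wall memory and configuration) to a JSON document and restores
#' it bit-exactly.
#'
#' @param model a `cognav_model`.
#' @param path file path; `write_model` creates it.
#' @export
write_model <- function(model, path) {
  flat <- function(x) list(dim = dim(x), data = as.vector(x))
  snap <- list(
    colors = model$colors,
    A_o = flat(model$A_o), A_p = flat(model$A_p), B_s = flat(model$B_s),
    B_p = flat(model$B_p), poses = flat(model$poses),
    walls = flat(model$walls),
    state_pose = model$state_pose, pose_state = model$pose_state,
    config = model$config[setdiff(names(model$config), "pref_color")],
    pref_color = model$config$pref_color)
  jsonlite::write_json(snap, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_model
#' @return `read_model` returns the restored `cognav_model`.
#' @export
read_model <- function(path) {
  snap <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(cognav_config, c(snap$config[names(snap$config) %in%
                                                names(formals(cognav_config))],
                                  list(pref_color = snap$pref_color)))
  unflat <- function(x, mode = "double") array(as.vector(x$data, mode), x$dim)
  model <- structure(list(
    config = cfg,
    colors = snap$colors,
    A_o = unflat(snap$A_o),
    poses = unflat(snap$poses, "integer"),
    A_p = unflat(snap$A_p),
    B_s = unflat(snap$B_s),
    B_p = unflat(snap$B_p, "integer"),
    state_pose = as.integer(snap$state_pose),
    pose_state = as.integer(snap$pose_state),
    walls = unflat(snap$walls, "logical")
  ), class = "cognav_model")
  dimnames(model$A_o) <- list(model$colors, NULL)
  dimnames(model$poses) <- list(NULL, c("u", "v"))
  dimnames(model$B_s) <- list(NULL, NULL, ACTIONS)
  dimnames(model$B_p) <- list(NULL, ACTIONS)
  dimnames(model$walls) <- list(NULL, c("N", "E", "S", "W"))
  model
}

#' Export the cognitive graph
#'
#' The learned map as a directed graph: one vertex per state (with its
#' bound internal pose and most likely color), one edge per confident
#' transition `(state, action, state')` with its normalized probability.
#'
#' @param model a `cognav_model`.
#' @param path optional file path; if given, the graph is written in GraphML
#'   (a standard graph interchange format).
#' @return an `igraph` object (invisibly when `path` is given); also
#'   available as a plain edge-list data frame in the graph's attributes via
#'   [cognitive_edges()].
#' @export
cognitive_graph <- function(model, path = NULL) {
  ed <- cognitive_edges(model)
  g <- igraph::graph_from_data_frame(
    ed, directed = TRUE,
    vertices = data.frame(
      name = seq_len(n_states(model)),
      u = model$poses[ifelse(is.na(model$state_pose), 1L, model$state_pose), 1],
      v = model$poses[ifelse(is.na(model$state_pose), 1L, model$state_pose), 2],
      color = model$colors[apply(model$A_o, 2, which.max)]))
  if (!is.null(path)) {
    igraph::write_graph(g, path, format = "graphml")
    return(invisible(g))
  }
  g
}

#' @rdname cognitive_graph
#' @return `cognitive_edges`: data frame with `from`, `action`, `to`,
#'   `probability` for every argmax transition the planner would use.
#' @export
cognitive_edges <- function(model) {
  succ <- argmax_graph(model)
  rows <- list()
  for (s in seq_len(n_states(model))) for (a in c("N", "E", "S", "W")) {
    s2 <- succ[s, a]
    if (is.na(s2)) next
    rows[[length(rows) + 1L]] <- data.frame(
      from = s, to = s2, action = a,
      probability = trans_likelihood(model, a)[s2, s])
  }
  if (!length(rows))
    return(data.frame(from = integer(), to = integer(),
                      action = character(), probability = numeric()))
  do.call(rbind, rows)
}
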