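#' Corridor map for spreading-activation planning
#'
#' Describes a maze as a graph of corridor segments: positions live on the
#' nodes and along the edges, distances are path lengths along the corridors
#' (the l1 metric for axis-aligned corridors, since the agent moves along
#' the corridor centers), and goals sit on nodes with associated reward
#' sizes.
#'
#' @param nodes character vector of node names.
#' @param edges data.frame with columns `from`, `to`, `length` (> 0).
#' @param goals named numeric vector: rewards at goal nodes.
#' @param check_connected error on disconnected maps (default `TRUE`;
#'   disconnected components get infinite distances otherwise, i.e. zero
#'   spread).
#' @return an object of class `corridor_map` with node distance matrix `D`.
#' @export
corridor_map <- function(nodes, edges, goals, check_connected = TRUE) {
  stopifnot(all(edges$from %in% nodes), all(edges$to %in% nodes),
            all(edges$length > 0), all(names(goals) %in% nodes))
  n <- length(nodes)
  D <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(D) <- 0
  for (i in seq_len(nrow(edges))) {
    a <- edges$from[i]; b <- edges$to[i]
    D[a, b] <- min(D[a, b], edges$length[i])
    D[b, a] <- D[a, b]
  }
  # Floyd-Warshall all-pairs shortest corridor paths.
  for (k in nodes) for (i in nodes) for (j in nodes)
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  if (check_connected && any(!is.finite(D)))
    stop("corridor map is not connected")
  structure(list(nodes = nodes, edges = edges, goals = goals, D = D),
            class = "corridor_map")
}

# Discretize every edge into positions spaced ~`step`; returns a data.frame
# of positions (edge, offset, label) and a neighbor list for hill climbing.
corridor_positions <- function(map, step = 0.05) {
  pos <- list()
  for (i in seq_len(nrow(map$edges))) {
    len <- map$edges$length[i]
    n_seg <- max(1, round(len / step))
    offs <- seq(0, len, length.out = n_seg + 1)
    pos[[i]] <- data.frame(edge = i, offset = offs)
  }
  do.call(rbind, pos)
}

# Corridor distance from edge positions to every goal node.
position_goal_distances <- function(map, positions) {
  goals <- names(map$goals)
  out <- matrix(0, nrow(positions), length(goals),
                dimnames = list(NULL, goals))
  for (g in seq_along(goals)) {
    dg <- map$D[, goals[g]]
    e <- map$edges[positions$edge, ]
    out[, g] <- pmin(positions$offset + dg[e$from],
                     (e$length - positions$offset) + dg[e$to])
  }
  out
}

#' Spreading-activation activity map
#'
#' The steady-state activity contributed by each goal at a position `p` is
#' `r_g * exp(-d(p, g) / gamma_spread)` with corridor distance `d`; the
#' overall activity is the linear superposition over goals. Activity spreads
#' symmetrically along every corridor by default; the retrodromic variant
#' forbids spreading back through a designated origin node (distances must
#' then avoid paths through it).
#'
#' @param map a `corridor_map`.
#' @param gamma_spread attenuation length scale (> 0).
#' @param step spatial discretization of the corridors.
#' @param retrodromic_origin optional node name: activity may not spread
#'   through this node (paths through it are disallowed when computing
#'   distances).
#' @return data.frame of positions with columns `edge`, `offset`,
#'   `activity`; the attribute `"map"` carries the inputs.
#' @export
spreading_activation_map <- function(map, gamma_spread, step = 0.05,
                                     retrodromic_origin = NULL) {
  stopifnot(gamma_spread > 0)
  use_map <- map
  if (!is.null(retrodromic_origin)) {
    # Remove the origin node from pass-through paths: recompute distances on
    # the graph without it, then restore direct distances from the origin.
    keep <- setdiff(map$nodes, retrodromic_origin)
    sub_edges <- map$edges[map$edges$from %in% keep & map$edges$to %in% keep, ]
    submap <- corridor_map(keep, sub_edges,
                           map$goals[names(map$goals) %in% keep],
                           check_connected = FALSE)
    D <- map$D
    D[keep, keep] <- submap$D
    use_map$D <- D
  }
  positions <- corridor_positions(map, step)
  dists <- position_goal_distances(use_map, positions)
  act <- as.numeric(exp(-dists / gamma_spread) %*% map$goals[colnames(dists)])
  out <- cbind(positions, activity = act)
  attr(out, "map") <- map
  attr(out, "gamma_spread") <- gamma_spread
  out
}

#' Follow the activity gradient through the corridors
#'
#' Steepest-ascent walk along the corridor centers: from the current
#' position, move to the adjacent discretized position with the highest
#' activity, as long as it improves on the current one; stop at a local
#' maximum. At a junction node the agent chooses between whole corridors:
#' if no adjacent position improves but some incident corridor contains a
#' position more active than the junction itself, the agent traverses that
#' corridor to its activity maximum (linear superposition of several distant
#' goals can produce a shallow dip right at a junction, which a
#' corridor-level choice steps across). If the walk ends at a goal node, the
#' goal's reward is collected.
#'
#' @param activity_map result of [spreading_activation_map()].
#' @param start node name to start from.
#' @return list with `path` (data.frame of visited positions), `goal`
#'   (reached goal name or `NA`), `reward` (0 if no goal reached).
#' @export
gradient_path <- function(activity_map, start) {
  map <- attr(activity_map, "map")
  pos <- activity_map
  # Build adjacency between discretized positions: consecutive offsets on an
  # edge, plus cross-edge links through shared nodes.
  key_node <- function(i) {
    e <- map$edges[pos$edge[i], ]
    if (pos$offset[i] == 0) e$from
    else if (pos$offset[i] == e$length) e$to
    else NA_character_
  }
  node_of <- vapply(seq_len(nrow(pos)), key_node, character(1))
  neighbors <- function(i) {
    same <- which(pos$edge == pos$edge[i])
    offs <- pos$offset[same]
    o <- pos$offset[i]
    nb <- same[abs(offs - o) > 0 & abs(offs - o) <= min(diff(sort(unique(offs)))) + 1e-9]
    if (!is.na(node_of[i]))
      nb <- union(nb, setdiff(which(node_of == node_of[i]), i))
    # From a node, also step one position into every incident edge.
    if (!is.na(node_of[i])) {
      for (j in which(map$edges$from == node_of[i] | map$edges$to == node_of[i])) {
        cand <- which(pos$edge == j)
        ends <- pos$offset[cand]
        at_from <- map$edges$from[j] == node_of[i]
        want <- if (at_from) sort(ends)[2] else sort(ends, decreasing = TRUE)[2]
        nb <- union(nb, cand[ends == want])
      }
    }
    nb
  }
  start_i <- which(node_of == start)[1]
  if (is.na(start_i)) stop("start node not found on any edge")
  cur <- start_i
  path <- cur
  repeat {
    nb <- neighbors(cur)
    if (length(nb) == 0) break
    best <- nb[which.max(pos$activity[nb])]
    if (pos$activity[best] <= pos$activity[cur] + 1e-12) {
      # Junction lookahead: compare whole incident corridors.
      if (is.na(node_of[cur])) break
      inc <- which(map$edges$from == node_of[cur] |
                     map$edges$to == node_of[cur])
      cand <- NULL; cand_act <- pos$activity[cur] + 1e-12
      for (j in inc) {
        on_j <- which(pos$edge == j)
        top <- on_j[which.max(pos$activity[on_j])]
        if (pos$activity[top] > cand_act && !(top %in% path)) {
          cand <- top; cand_act <- pos$activity[top]
        }
      }
      if (is.null(cand)) break
      # traverse the chosen corridor to its activity maximum
      j <- pos$edge[cand]
      on_j <- which(pos$edge == j)
      at_from <- map$edges$from[j] == node_of[cur]
      seg <- if (at_from) on_j[order(pos$offset[on_j])]
             else on_j[order(-pos$offset[on_j])]
      seg <- seg[seq_len(which(seg == cand))]
      path <- c(path, seg[-1])
      cur <- cand
      next
    }
    cur <- best
    path <- c(path, cur)
    if (length(path) > 100 * nrow(pos)) stop("gradient walk failed to terminate")
  }
  goal <- NA_character_
  if (!is.na(node_of[cur]) && node_of[cur] %in% names(map$goals))
    goal <- node_of[cur]
  list(path = pos[path, c("edge", "offset", "activity")],
       goal = goal,
       reward = if (is.na(goal)) 0 else unname(map$goals[goal]))
}

#' Corridor map of the devaluation maze
#'
#' The reconstructed corridor layout of the three-decision-point maze: the
#' root connects to the left and right decision points by unit corridors;
#' the cheese (reward 4 at baseline, 2 devalued) hangs one unit off the left
#' decision point and the small reward 1 two units off it; the two
#' right-hand goals (rewards 3 and 2) hang one unit each off the right
#' decision point. All acceptance-level conclusions are robust to the
#' attenuation scale over at least `[0.5x, 2x]` its default.
#'
#' @param devalued if `TRUE` the cheese reward is 2.
#' @return a `corridor_map`; the attribute `"gamma_spread"` holds the default
#'   attenuation scale (1.2 x the second segment of the root-to-right path,
#'   i.e. 1.2 corridor units).
#' @export
devaluation_corridor_map <- function(devalued = FALSE) {
  edges <- data.frame(
    from = c("root", "root", "left", "left", "right", "right"),
    to = c("left", "right", "cheese", "small", "big3", "big2"),
    length = c(1, 1, 1, 2, 1, 1),
    stringsAsFactors = FALSE
  )
  goals <- c(cheese = if (devalued) 2 else 4, small = 1, big3 = 3, big2 = 2)
  map <- corridor_map(c("root", "left", "right", "cheese", "small",
                        "big3", "big2"), edges, goals)
  attr(map, "gamma_spread") <- 1.2
  map
}
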