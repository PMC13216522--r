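# Physical accessibility to screening centers: a linear-decay density of
# active centers within a 5000 m street-network radius. Shortest paths are
# computed with igraph on an undirected weighted graph; query points and
# centers are snapped to their nearest network node (the snap leg's
# Euclidean distance is ignored by default, see `add_snap_leg`).

#' Build an igraph street network from node/edge tables
#'
#' @param network list with `nodes` (node_id, x, y) and `edges`
#'   (from, to, length in meters, > 0)
#' @return an igraph object with edge weights in meters
#' @export
build_network_graph <- function(network) {
  nodes <- data.table::as.data.table(network$nodes)
  edges <- data.table::as.data.table(network$edges)
  assert_that(nrow(nodes) > 0L, "configuration error: empty street network")
  assert_that(all(edges$length > 0), "invalid network: edge lengths must be > 0")
  g <- igraph::graph_from_data_frame(
    edges[, .(from = as.character(from), to = as.character(to))],
    directed = FALSE,
    vertices = data.frame(name = as.character(nodes$node_id)))
  igraph::E(g)$weight <- edges$length
  g
}

# shortest-path distances between (possibly duplicated) node id vectors
node_distances <- function(graph, from_nodes, to_nodes) {
  uf <- unique(from_nodes); ut <- unique(to_nodes)
  D <- igraph::distances(graph, v = as.character(uf), to = as.character(ut))
  D[match(from_nodes, uf), match(to_nodes, ut), drop = FALSE]
}

#' Snap points to the nearest network node
#'
#' Nearest by Euclidean distance; exact ties go to the smallest node id.
#'
#' @param points matrix or data.frame with x, y columns
#' @param network node/edge list
#' @return integer vector of node ids
#' @export
snap_to_node <- function(points, network) {
  nodes <- data.table::as.data.table(network$nodes)
  assert_that(nrow(nodes) > 0L, "configuration error: empty street network")
  pts <- as.matrix(as.data.frame(points)[, c("x", "y")])
  nd <- as.matrix(nodes[, .(x, y)])
  # order nodes by id so that among equidistant nodes FNN returns the
  # smallest id is not guaranteed; resolve ties explicitly
  kn <- FNN::get.knnx(nd, pts, k = min(4L, nrow(nd)))
  out <- integer(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    d <- kn$nn.dist[i, ]
    cand <- kn$nn.index[i, abs(d - d[1]) <= 1e-9]
    out[i] <- min(nodes$node_id[cand])
  }
  out
}

#' Linear-decay accessibility score at query points
#'
#' For each query point, sums `1 - d/radius` over all active centers whose
#' street-network shortest-path distance `d` is at most `radius`; centers
#' beyond the radius (or unreachable) contribute 0.
#'
#' @param points data.frame with x, y (query locations)
#' @param centers data.frame with x, y of the active centers
#' @param network node/edge list
#' @param radius decay radius in meters (default 5000)
#' @param graph optional prebuilt [build_network_graph()] result
#' @param add_snap_leg add the Euclidean snap distance of the query point
#'   and center to the network distance (default FALSE)
#' @return numeric vector of scores (>= 0)
#' @export
access_score <- function(points, centers, network, radius = 5000,
                         graph = NULL, add_snap_leg = FALSE) {
  if (nrow(centers) == 0L) return(rep(0, nrow(points)))
  if (is.null(graph)) graph <- build_network_graph(network)
  pn <- snap_to_node(points, network)
  cn <- snap_to_node(centers, network)
  D <- node_distances(graph, pn, cn)
  if (add_snap_leg) {
    nodes <- data.table::as.data.table(network$nodes)
    data.table::setkey(nodes, node_id)
    leg_p <- sqrt((points$x - nodes[.(pn), x])^2 + (points$y - nodes[.(pn), y])^2)
    leg_c <- sqrt((centers$x - nodes[.(cn), x])^2 + (centers$y - nodes[.(cn), y])^2)
    D <- D + outer(leg_p, leg_c, `+`)
  }
  contrib <- 1 - D / radius
  contrib[contrib < 0 | !is.finite(D)] <- 0 # beyond radius or unreachable
  if (any(!is.finite(D))) {
    warning(sum(!is.finite(D)), " unreachable point-center pairs treated as beyond radius")
  }
  unname(rowSums(contrib))
}

#' Per-point, per-period accessibility panel
#'
#' A center contributes to a period when the period label lies within its
#' `[first_active_period, last_active_period]` interval.
#'
#' @param points data.frame with id, x, y (e.g., neighborhood centroids)
#' @param centers data.frame with x, y, first_active_period,
#'   last_active_period
#' @param network node/edge list
#' @param periods period labels
#' @param radius decay radius in meters
#' @return matrix of scores, `nrow(points)` x `length(periods)` with
#'   period labels as column names
#' @export
access_panel <- function(points, centers, network, periods, radius = 5000) {
  centers <- data.table::as.data.table(centers)
  assert_that(all(centers$last_active_period >= centers$first_active_period),
              "validation error: center closure precedes opening")
  graph <- build_network_graph(network)
  out <- matrix(0, nrow(points), length(periods),
                dimnames = list(NULL, as.character(periods)))
  # distances are period-invariant: compute once, mask by activity
  if (nrow(centers) > 0L) {
    pn <- snap_to_node(points, network)
    cn <- snap_to_node(centers, network)
    D <- node_distances(graph, pn, cn)
    contrib <- 1 - D / radius
    contrib[contrib < 0 | !is.finite(D)] <- 0
    for (t in seq_along(periods)) {
      act <- centers$first_active_period <= periods[t] &
             centers$last_active_period >= periods[t]
      if (any(act)) out[, t] <- rowSums(contrib[, act, drop = FALSE])
    }
  }
  out
}
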