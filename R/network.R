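#' Build a drive-time road network
#'
#' Converts road line segments with length and design-speed attributes into an
#' undirected, travel-time-weighted graph. Each segment becomes one edge whose
#' weight is its traversal time in minutes, `60 * length_km / speed_kmh`.
#' Segment endpoints are the graph nodes: coordinates are rounded to 1 mm, and
#' endpoints identical after rounding merge into a single node, which is how
#' intersecting segments become connected.
#'
#' Travel is undirected (no one-way streets) and attaching a community or
#' population block to the network (see [snap_to_node()]) costs nothing: both
#' are deliberate simplifications suited to sparse rural road data.
#'
#' @param line_features A data frame with one row per road segment and columns
#'   `x1, y1, x2, y2` (endpoint coordinates, metres, in a shared planar CRS)
#'   plus `length_km` and `speed_kmh`, both strictly positive.
#' @return An object of class `road_network`: a list with `nodes` (data frame
#'   `node_id, x, y`), `edges` (data frame `from, to, minutes`) and `graph`
#'   (the underlying [igraph][igraph::igraph-package] object).
#' @export
#' @examples
#' seg <- data.frame(x1 = 0, y1 = 0, x2 = 100e3, y2 = 0,
#'                   length_km = 100, speed_kmh = 100)
#' net <- build_graph(seg)
#' net$edges$minutes  # 60
build_graph <- function(line_features) {
  needed <- c("x1", "y1", "x2", "y2", "length_km", "speed_kmh")
  missing_cols <- setdiff(needed, names(line_features))
  if (length(missing_cols) > 0) {
    ssm_abort("line features missing column(s): ",
              paste(missing_cols, collapse = ", "))
  }
  lf <- line_features
  if (nrow(lf) == 0) ssm_abort("no road segments supplied")
  if (any(!is.finite(lf$length_km)) || any(lf$length_km <= 0)) {
    ssm_abort("every segment needs length_km > 0")
  }
  if (any(!is.finite(lf$speed_kmh)) || any(lf$speed_kmh <= 0)) {
    ssm_abort("every segment needs speed_kmh > 0")
  }

  # node identity: coordinates rounded to 1 mm
  key_a <- paste(round(lf$x1, 3), round(lf$y1, 3))
  key_b <- paste(round(lf$x2, 3), round(lf$y2, 3))
  keys <- unique(c(key_a, key_b))
  ids <- sprintf("n%06d", seq_along(keys))
  names(ids) <- keys

  xy <- do.call(rbind, lapply(strsplit(keys, " ", fixed = TRUE), as.numeric))
  nodes <- data.frame(node_id = unname(ids), x = xy[, 1], y = xy[, 2],
                      stringsAsFactors = FALSE)

  edges <- data.frame(
    from = unname(ids[key_a]),
    to = unname(ids[key_b]),
    minutes = 60 * lf$length_km / lf$speed_kmh,
    stringsAsFactors = FALSE
  )
  if (any(edges$from == edges$to)) {
    ssm_abort("degenerate segment: both endpoints round to the same node")
  }

  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes$node_id)
  igraph::E(g)$weight <- edges$minutes

  structure(list(nodes = nodes, edges = edges, graph = g,
                 segments = lf[, needed]),
            class = "road_network")
}

#' @export
print.road_network <- function(x, ...) {
  cat(sprintf("<road_network> %d nodes, %d edges, %.1f total network minutes\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$minutes)))
  invisible(x)
}

#' Snap a point to its nearest network node
#'
#' Returns the node identifier minimizing Euclidean distance to the point;
#' ties are broken by the lexicographically smallest node identifier, so the
#' result is deterministic.
#'
#' @param network A `road_network`.
#' @param point Numeric length-2 vector `c(x, y)` in the network's CRS.
#' @return A node identifier (character scalar).
#' @export
snap_to_node <- function(network, point) {
  stopifnot(inherits(network, "road_network"))
  if (nrow(network$nodes) == 0) ssm_abort("cannot snap to an empty network")
  if (!is.numeric(point) || length(point) != 2 || anyNA(point)) {
    ssm_abort("point must be a numeric (x, y) pair")
  }
  d2 <- (network$nodes$x - point[1])^2 + (network$nodes$y - point[2])^2
  hits <- network$nodes$node_id[d2 == min(d2)]
  sort(hits)[1]
}

node_index <- function(network, node) {
  idx <- match(node, network$nodes$node_id)
  if (anyNA(idx)) {
    ssm_abort("unknown node(s): ", paste(node[is.na(idx)], collapse = ", "))
  }
  idx
}

#' Shortest travel time between two nodes
#'
#' Least-minutes path cost over the weighted graph. Disconnection is a
#' first-class value: `Inf`, never an error, so downstream scoring can map it
#' to maximal isolation.
#'
#' @param network A `road_network`.
#' @param origin_node,dest_node Node identifiers.
#' @return Minutes as a non-negative number, or `Inf` if unreachable.
#' @export
travel_time_minutes <- function(network, origin_node, dest_node) {
  stopifnot(inherits(network, "road_network"))
  node_index(network, c(origin_node, dest_node))
  as.numeric(igraph::distances(network$graph, v = origin_node,
                               to = dest_node, algorithm = "dijkstra"))
}

#' Drive-time service area
#'
#' All nodes reachable from the origin within the minute budget (inclusive
#' `<=`); always contains the origin.
#'
#' @param network A `road_network`.
#' @param origin_node Node identifier.
#' @param limit_minutes Non-negative drive-time budget; `Inf` allowed.
#' @return Character vector of node identifiers.
#' @export
service_area <- function(network, origin_node, limit_minutes) {
  stopifnot(inherits(network, "road_network"))
  node_index(network, origin_node)
  if (!is.numeric(limit_minutes) || length(limit_minutes) != 1 ||
      is.na(limit_minutes) || limit_minutes < 0) {
    ssm_abort("limit_minutes must be a single non-negative number")
  }
  d <- igraph::distances(network$graph, v = origin_node,
                         algorithm = "dijkstra")[1, ]
  names(d)[d <= limit_minutes]
}

#' Travel time to the nearest site
#'
#' Finds the closest of a set of candidate site nodes (e.g. palliative care
#' centres) by network travel time. Ties are broken by the smallest site
#' identifier. When no site is reachable the result carries `minutes = Inf`
#' and `target = NA`.
#'
#' @param network A `road_network`.
#' @param origin_node Node identifier.
#' @param site_nodes Non-empty character vector of node identifiers.
#' @return A list with `target` (node identifier or `NA`) and `minutes`.
#' @export
nearest_site_minutes <- function(network, origin_node, site_nodes) {
  stopifnot(inherits(network, "road_network"))
  if (length(site_nodes) == 0) ssm_abort("site_nodes must be non-empty")
  site_nodes <- unique(site_nodes)
  node_index(network, c(origin_node, site_nodes))
  d <- igraph::distances(network$graph, v = origin_node, to = site_nodes,
                         algorithm = "dijkstra")[1, ]
  best <- min(d)
  if (is.infinite(best)) {
    return(list(target = NA_character_, minutes = Inf))
  }
  hits <- site_nodes[d == best]
  list(target = sort(hits)[1], minutes = as.numeric(best))
}
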