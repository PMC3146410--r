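#' Road classes recognized by the speed model
#'
#' Three-level classification used to assign legal car speeds to road
#' segments: toll roads, national or principal local roads, and all others.
#'
#' @format Character vector of length 3.
#' @export
ROAD_CLASSES <- c("toll", "national_or_principal", "other")

#' Speed table for the road-class travel model
#'
#' Legal car speed limits by road class, in km/h. Defaults are 80 km/h for
#' toll roads, 60 km/h for national or principal local roads, and 40 km/h
#' for all other roads.
#'
#' @param toll speed on toll roads, km/h
#' @param national_or_principal speed on national or principal local roads, km/h
#' @param other speed on all remaining roads, km/h
#' @return Named numeric vector of class `speed_table`.
#' @examples
#' speed_table()
#' speed_table(other = 30)
#' @export
speed_table <- function(toll = 80, national_or_principal = 60, other = 40) {
  s <- c(toll = toll, national_or_principal = national_or_principal,
         other = other)
  if (!all(is.finite(s)) || any(s <= 0))
    stop("all speeds must be finite and > 0", call. = FALSE)
  structure(s, class = "speed_table")
}

as_speed_table <- function(speeds) {
  if (inherits(speeds, "speed_table")) return(speeds)
  if (is.numeric(speeds) && all(ROAD_CLASSES %in% names(speeds)))
    return(do.call(speed_table, as.list(speeds[ROAD_CLASSES])))
  stop("`speeds` must be a speed_table or a named vector covering all road classes",
       call. = FALSE)
}

#' Construct a validated table of road segments
#'
#' @param ax,ay,bx,by endpoint coordinates in projected planar meters
#' @param road_class one of [ROAD_CLASSES] per segment (recycled)
#' @param length_m segment length in meters; where `NA`, the Euclidean
#'   endpoint distance is used
#' @param seg_id segment identifiers; defaults to `s1, s2, ...`
#' @return `data.frame` with columns `seg_id, ax, ay, bx, by, length_m,
#'   road_class`.
#' @export
road_segments <- function(ax, ay, bx, by, road_class = "other",
                          length_m = NA_real_, seg_id = NULL) {
  n <- length(ax)
  if (n == 0L) stop("empty segment list", call. = FALSE)
  coords <- cbind(ax, ay, bx, by)
  if (!all(is.finite(coords))) stop("non-finite segment coordinates", call. = FALSE)
  road_class <- rep_len(as.character(road_class), n)
  bad <- setdiff(unique(road_class), ROAD_CLASSES)
  if (length(bad))
    stop("unknown road_class value(s): ", paste(bad, collapse = ", "), call. = FALSE)
  length_m <- rep_len(as.numeric(length_m), n)
  eucl <- sqrt((bx - ax)^2 + (by - ay)^2)
  length_m[is.na(length_m)] <- eucl[is.na(length_m)]
  if (any(length_m <= 0))
    stop("segment lengths must be > 0 (degenerate segment endpoints?)", call. = FALSE)
  if (is.null(seg_id)) seg_id <- paste0("s", seq_len(n))
  data.frame(seg_id = as.character(seg_id), ax = ax, ay = ay, bx = bx, by = by,
             length_m = length_m, road_class = road_class,
             stringsAsFactors = FALSE)
}

# Merge a set of 2-D points into nodes, fusing points closer than `tol`.
# Returns integer node index per point plus the node coordinate matrix.
# Greedy in input order with a cell hash, so deterministic.
merge_endpoints <- function(pts, tol) {
  n <- nrow(pts)
  if (tol <= 0) {
    key <- paste(pts[, 1], pts[, 2], sep = "|")
    ukey <- unique(key)
    return(list(node = match(key, ukey),
                coords = pts[!duplicated(key), , drop = FALSE]))
  }
  node <- integer(n)
  coords <- matrix(NA_real_, n, 2)
  nn <- 0L
  cell_of <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(n)) {
    p <- pts[i, ]
    cx <- floor(p[1] / tol); cy <- floor(p[2] / tol)
    best <- 0L; bestd <- Inf
    for (dx in -1:1) for (dy in -1:1) {
      k <- paste(cx + dx, cy + dy, sep = "|")
      for (j in cell_of[[k]]) {
        d <- sqrt(sum((coords[j, ] - p)^2))
        if (d <= tol && (d < bestd || (d == bestd && j < best))) {
          best <- j; bestd <- d
        }
      }
    }
    if (best > 0L) {
      node[i] <- best
    } else {
      nn <- nn + 1L
      coords[nn, ] <- p
      k <- paste(cx, cy, sep = "|")
      cell_of[[k]] <- c(cell_of[[k]], nn)
      node[i] <- nn
    }
  }
  list(node = node, coords = coords[seq_len(nn), , drop = FALSE])
}

#' Build a routable road network from segments
#'
#' Endpoints closer than `snap_tolerance` meters are merged into a single
#' node; the result is an undirected graph whose edges carry length and
#' road class. Connected components are labelled so that unreachable
#' origin-destination pairs can be diagnosed.
#'
#' @param segments a data.frame as returned by [road_segments()]
#' @param snap_tolerance endpoint merge tolerance in meters (default 0.5,
#'   enough to absorb digitization jitter without collapsing real
#'   intersections)
#' @param quiet suppress the component-count message
#' @return An object of class `road_network`: a list with the `igraph`
#'   graph, the node coordinate matrix, and component labels.
#' @examples
#' sq <- road_segments(ax = c(0, 1, 1, 0), ay = c(0, 0, 1, 1),
#'                     bx = c(1, 1, 0, 0), by = c(0, 1, 1, 0))
#' net <- build_network(sq, snap_tolerance = 0)
#' @export
build_network <- function(segments, snap_tolerance = 0.5, quiet = FALSE) {
  if (!is.data.frame(segments) || nrow(segments) == 0L)
    stop("empty segment list", call. = FALSE)
  if (!is.numeric(snap_tolerance) || snap_tolerance < 0)
    stop("snap_tolerance must be >= 0", call. = FALSE)
  segments <- road_segments(segments$ax, segments$ay, segments$bx, segments$by,
                            segments$road_class, segments$length_m,
                            segments$seg_id)
  pts <- rbind(as.matrix(segments[, c("ax", "ay")]),
               as.matrix(segments[, c("bx", "by")]))
  colnames(pts) <- c("x", "y")
  m <- merge_endpoints(pts, snap_tolerance)
  n_seg <- nrow(segments)
  a <- m$node[seq_len(n_seg)]
  b <- m$node[n_seg + seq_len(n_seg)]
  collapsed <- a == b
  if (any(collapsed)) {
    warning(sum(collapsed), " segment(s) collapsed by endpoint merging; dropped",
            call. = FALSE)
    if (all(collapsed)) stop("all segments collapsed by endpoint merging", call. = FALSE)
    a <- a[!collapsed]; b <- b[!collapsed]
    segments <- segments[!collapsed, , drop = FALSE]
  }
  g <- igraph::make_empty_graph(n = nrow(m$coords), directed = FALSE)
  g <- igraph::add_edges(g, rbind(a, b))
  igraph::E(g)$length_m <- segments$length_m
  igraph::E(g)$road_class <- segments$road_class
  igraph::E(g)$seg_id <- segments$seg_id
  comp <- igraph::components(g)
  if (!quiet)
    message("road network: ", igraph::vcount(g), " nodes, ",
            igraph::ecount(g), " edges, ", comp$no, " component(s)")
  structure(list(graph = g, coords = m$coords,
                 component = comp$membership, n_components = comp$no),
            class = "road_network")
}

#' @export
print.road_network <- function(x, ...) {
  cat("road_network:", igraph::vcount(x$graph), "nodes,",
      igraph::ecount(x$graph), "edges,", x$n_components, "component(s)\n")
  invisible(x)
}

#' Travel time along a road segment
#'
#' Converts a segment length and a car speed into minutes of driving:
#' `(length/1000) / speed * 60`. A 100 m hop on a 60 km/h road takes 0.1
#' minutes (6 seconds).
#'
#' @param length_m length in meters (vectorized)
#' @param speed_kmh speed in km/h (vectorized)
#' @return travel time in minutes
#' @examples
#' segment_travel_time(100, 60)    # 0.1 min
#' segment_travel_time(80000, 80)  # one hour
#' @export
segment_travel_time <- function(length_m, speed_kmh) {
  if (any(length_m < 0)) stop("length must be >= 0", call. = FALSE)
  if (any(!is.finite(speed_kmh)) || any(speed_kmh <= 0))
    stop("speed must be > 0", call. = FALSE)
  (length_m / 1000) / speed_kmh * 60
}

# per-edge travel time in minutes under a speed table
edge_times <- function(network, speeds) {
  speeds <- as_speed_table(speeds)
  segment_travel_time(igraph::E(network$graph)$length_m,
                      unclass(speeds)[igraph::E(network$graph)$road_class])
}

edge_weights <- function(network, weight, speeds) {
  switch(weight,
         distance = igraph::E(network$graph)$length_m,
         time = edge_times(network, speeds),
         stop("weight must be 'distance' or 'time'", call. = FALSE))
}

# Path-selection weights: the primary metric plus an epsilon of the other
# one, so that among primary-minimizing routes the one best on the secondary
# metric is chosen deterministically (grids have many equal-length routes
# whose travel times differ). Epsilons are far below any meaningful gap in
# the primary metric (<= 1e-3 m resp. <= 1e-3 min on a 1000 km network).
routing_weights <- function(network, weight, speeds) {
  len <- igraph::E(network$graph)$length_m
  tmin <- edge_times(network, speeds)
  if (weight == "distance") len + 1e-6 * tmin else tmin + 1e-9 * len
}

#' Shortest path between two network nodes
#'
#' Minimizes either network distance or travel time; reports both the
#' total distance (km) and total time (minutes) accumulated along the
#' returned path. When several paths minimize the chosen weight, the one
#' best on the other metric is returned, so the reported pair is
#' deterministic.
#'
#' @param network a [build_network()] result
#' @param src,dst node indices
#' @param weight `"distance"` (default) or `"time"` — the quantity the path
#'   minimizes
#' @param speeds a [speed_table()]
#' @return list with `path` (node indices), `distance_km`, `time_min`.
#' @export
shortest_path <- function(network, src, dst, weight = c("distance", "time"),
                          speeds = speed_table()) {
  weight <- match.arg(weight)
  nv <- igraph::vcount(network$graph)
  if (!(src %in% seq_len(nv)) || !(dst %in% seq_len(nv)))
    stop("src and dst must be existing node indices", call. = FALSE)
  if (src == dst)
    return(list(path = src, distance_km = 0, time_min = 0))
  if (network$component[src] != network$component[dst])
    stop("nodes ", src, " and ", dst, " are in different network components; ",
         "no route exists", call. = FALSE)
  w <- routing_weights(network, weight, speeds)
  sp <- igraph::shortest_paths(network$graph, from = src, to = dst,
                               weights = w, output = "both")
  ep <- sp$epath[[1]]
  tmin <- edge_times(network, speeds)
  list(path = as.integer(sp$vpath[[1]]),
       distance_km = sum(igraph::E(network$graph)$length_m[ep]) / 1000,
       time_min = sum(tmin[ep]))
}

#' Snap a point to the nearest network node
#'
#' Euclidean nearest node; ties are broken by the lowest node index, so the
#' result is deterministic.
#'
#' @param network a [build_network()] result
#' @param point numeric length-2 vector `(x, y)` in planar meters, or an
#'   n x 2 matrix of points
#' @return node index (or integer vector for a matrix of points)
#' @export
snap_point <- function(network, point) {
  if (is.matrix(point) || is.data.frame(point)) {
    pts <- as.matrix(point)
    return(vapply(seq_len(nrow(pts)),
                  function(i) snap_point(network, pts[i, ]), integer(1)))
  }
  if (length(point) != 2 || !all(is.finite(point)))
    stop("point must be a finite (x, y) pair", call. = FALSE)
  d2 <- (network$coords[, 1] - point[1])^2 + (network$coords[, 2] - point[2])^2
  which.min(d2)  # first minimum = lowest node index
}
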