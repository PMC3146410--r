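#' Construct a table of demand blocks
#'
#' A demand block is a census-block centroid carrying the count of the
#' population it represents (children aged 0-14 in the pediatric-care use
#' case). Zero-population blocks are allowed through I/O but excluded from
#' all weighted statistics.
#'
#' @param block_id identifiers
#' @param x,y centroid coordinates in projected planar meters
#' @param population nonnegative counts
#' @return data.frame `block_id, x, y, population`
#' @export
demand_blocks <- function(block_id, x, y, population) {
  if (any(!is.finite(c(x, y)))) stop("non-finite block coordinates", call. = FALSE)
  if (any(!is.finite(population)) || any(population < 0))
    stop("population must be >= 0", call. = FALSE)
  data.frame(block_id = as.character(block_id), x = x, y = y,
             population = population, stringsAsFactors = FALSE)
}

#' Construct a table of facilities
#'
#' @param facility_id identifiers
#' @param x,y locations in projected planar meters
#' @param region_id optional region membership label
#' @return data.frame `facility_id, x, y, region_id`
#' @export
facilities <- function(facility_id, x, y, region_id = NA_character_) {
  if (any(!is.finite(c(x, y)))) stop("non-finite facility coordinates", call. = FALSE)
  data.frame(facility_id = as.character(facility_id), x = x, y = y,
             region_id = rep_len(as.character(region_id), length(x)),
             stringsAsFactors = FALSE)
}

#' Assign every demand block to its nearest facility
#'
#' For each block the facility minimizing the chosen weight (network
#' distance by default, travel time optionally) over shortest paths is
#' selected. All facilities are candidates regardless of any region
#' membership — a block near a regional boundary may be served from the
#' neighboring region. Block centroids and facilities are snapped to the
#' nearest network node before routing; no approach distance is added.
#' Ties are broken by the lowest facility_id.
#'
#' In `mode = "euclidean"` the network is bypassed entirely: distances are
#' straight-line, and times are the straight-line distance driven at the
#' `"other"` class speed. This is a fast exploration mode; the inequality
#' statistic D is scale invariant, so D is identical whether computed on
#' Euclidean distances or on those nominal times.
#'
#' @param network a [build_network()] result (may be `NULL` in euclidean mode)
#' @param blocks a [demand_blocks()] data.frame
#' @param facs a [facilities()] data.frame
#' @param weight `"distance"` (default) or `"time"` — what the choice of
#'   nearest facility minimizes
#' @param speeds a [speed_table()]
#' @param mode `"network"` (default) or `"euclidean"`
#' @param quiet suppress the zero-population message
#' @return An `access_result` data.frame with one row per block:
#'   `block_id, facility_id, distance_km, time_min, population`.
#' @export
assign_nearest <- function(network, blocks, facs,
                           weight = c("distance", "time"),
                           speeds = speed_table(),
                           mode = c("network", "euclidean"),
                           quiet = FALSE) {
  weight <- match.arg(weight)
  mode <- match.arg(mode)
  if (nrow(facs) == 0L) stop("at least one facility required", call. = FALSE)
  if (!any(blocks$population > 0))
    stop("at least one block with population > 0 required", call. = FALSE)
  speeds <- as_speed_table(speeds)
  # order candidates by id so the first minimum is the lowest facility_id
  facs <- facs[order(facs$facility_id), , drop = FALSE]

  if (mode == "euclidean") {
    dx <- outer(blocks$x, facs$x, "-")
    dy <- outer(blocks$y, facs$y, "-")
    dmat <- sqrt(dx^2 + dy^2)                   # blocks x facilities, meters
    j <- apply(dmat, 1L, which.min)
    dist_m <- dmat[cbind(seq_len(nrow(blocks)), j)]
    res <- data.frame(block_id = blocks$block_id,
                      facility_id = facs$facility_id[j],
                      distance_km = dist_m / 1000,
                      time_min = segment_travel_time(dist_m, unclass(speeds)[["other"]]),
                      population = blocks$population,
                      stringsAsFactors = FALSE)
  } else {
    if (is.null(network)) stop("network mode requires a road network", call. = FALSE)
    bnode <- snap_point(network, cbind(blocks$x, blocks$y))
    fnode <- snap_point(network, cbind(facs$x, facs$y))
    w <- edge_weights(network, weight, speeds)
    ub <- sort(unique(bnode))
    dmat <- igraph::distances(network$graph, v = fnode, to = ub, weights = w)
    dmat <- dmat[, match(bnode, ub), drop = FALSE]   # facilities x blocks
    best <- apply(dmat, 2L, which.min)
    unreachable <- !is.finite(dmat[cbind(best, seq_along(bnode))])
    if (any(unreachable))
      stop("block(s) unreachable from every facility: ",
           paste(blocks$block_id[unreachable], collapse = ", "), call. = FALSE)
    # accumulate true distance AND time along the weight-minimizing path;
    # path extraction uses the tie-broken routing weights so the reported
    # pair does not depend on which equal-weight route igraph visits first
    rw <- routing_weights(network, weight, speeds)
    tmin <- edge_times(network, speeds)
    len <- igraph::E(network$graph)$length_m
    dist_m <- numeric(nrow(blocks))
    time_m <- numeric(nrow(blocks))
    for (f in unique(best)) {
      idx <- which(best == f)
      targ <- unique(bnode[idx])
      sp <- igraph::shortest_paths(network$graph, from = fnode[f], to = targ,
                                   weights = rw, output = "epath")
      dsum <- vapply(sp$epath, function(e) sum(len[e]), numeric(1))
      tsum <- vapply(sp$epath, function(e) sum(tmin[e]), numeric(1))
      pos <- match(bnode[idx], targ)
      dist_m[idx] <- dsum[pos]
      time_m[idx] <- tsum[pos]
    }
    res <- data.frame(block_id = blocks$block_id,
                      facility_id = facs$facility_id[best],
                      distance_km = dist_m / 1000,
                      time_min = time_m,
                      population = blocks$population,
                      stringsAsFactors = FALSE)
  }
  nzero <- sum(blocks$population == 0)
  if (nzero > 0 && !quiet)
    message(nzero, " block(s) with population 0 carried through; ",
            "excluded from weighted statistics")
  class(res) <- c("access_result", "data.frame")
  res
}

#' Population-weighted mean access time
#'
#' The sum of each person's travel time divided by the total population:
#' `sum(w_i x_i) / sum(w_i)` over blocks with positive population.
#'
#' @param result an `access_result` from [assign_nearest()]
#' @return mean travel time in minutes
#' @export
mean_access_time <- function(result) {
  w <- result$population
  if (sum(w) <= 0) stop("total population is zero", call. = FALSE)
  sum(w * result$time_min) / sum(w)
}
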