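# All readers require projected planar coordinates in meters. A coordinate
# set that fits entirely inside the longitude/latitude box is almost
# certainly geographic and would break every distance in the pipeline,
# so it is rejected outright rather than silently mangled.
assert_projected <- function(x, y, what) {
  if (length(x) && all(abs(x) <= 180) && all(abs(y) <= 90))
    stop(what, ": coordinates look like geographic lon/lat degrees; ",
         "project them to planar meters first", call. = FALSE)
  invisible(TRUE)
}

is_geojson <- function(path) {
  if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE)) return(TRUE)
  head <- readChar(path, 64L, useBytes = TRUE)
  grepl("^\\s*\\{", head)
}

read_geojson_features <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection: ", path,
                                 call. = FALSE)
  gj$features
}

feature_points <- function(features, props) {
  coords <- t(vapply(features, function(f) {
    if (!identical(f$geometry$type, "Point"))
      stop("expected Point geometries", call. = FALSE)
    as.numeric(unlist(f$geometry$coordinates)[1:2])
  }, numeric(2)))
  vals <- lapply(props, function(p)
    sapply(features, function(f) {
      v <- f$properties[[p]]
      if (is.null(v)) NA else v
    }))
  names(vals) <- props
  cbind(data.frame(x = coords[, 1], y = coords[, 2]),
        as.data.frame(vals, stringsAsFactors = FALSE))
}

#' Read demand blocks from CSV or GeoJSON
#'
#' CSV needs columns `block_id, x, y, population`; GeoJSON needs Point
#' features with `block_id` and `population` properties. Coordinates must
#' be projected planar meters.
#'
#' @param path file path
#' @return a [demand_blocks()] data.frame
#' @export
read_blocks <- function(path) {
  if (is_geojson(path)) {
    d <- feature_points(read_geojson_features(path), c("block_id", "population"))
  } else {
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  assert_projected(d$x, d$y, "blocks")
  demand_blocks(d$block_id, d$x, d$y, as.numeric(d$population))
}

#' Read facilities from CSV or GeoJSON
#'
#' CSV needs `facility_id, x, y` and optionally `region_id`; GeoJSON needs
#' Point features with a `facility_id` property.
#'
#' @param path file path
#' @return a [facilities()] data.frame
#' @export
read_facilities <- function(path) {
  if (is_geojson(path)) {
    d <- feature_points(read_geojson_features(path),
                        c("facility_id", "region_id"))
  } else {
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (is.null(d$region_id)) d$region_id <- NA_character_
  }
  assert_projected(d$x, d$y, "facilities")
  facilities(d$facility_id, d$x, d$y, d$region_id)
}

#' Read road segments from an edge-list CSV or a GeoJSON of LineStrings
#'
#' CSV columns: `seg_id, ax, ay, bx, by, length_m, road_class` (`length_m`
#' may be empty; it is then computed from the endpoints). GeoJSON
#' LineString features carry a `road_class` property and are decomposed
#' into one segment per consecutive vertex pair. `class_aliases` maps
#' nonstandard class labels onto [ROAD_CLASSES].
#'
#' @param path file path
#' @param class_aliases named character vector, e.g.
#'   `c(highway = "toll", trunk = "national_or_principal")`
#' @return segment data.frame as from [road_segments()]
#' @export
read_segments <- function(path, class_aliases = NULL) {
  if (is_geojson(path)) {
    features <- read_geojson_features(path)
    segs <- do.call(rbind, lapply(seq_along(features), function(i) {
      f <- features[[i]]
      if (!identical(f$geometry$type, "LineString"))
        stop("expected LineString geometries", call. = FALSE)
      cc <- do.call(rbind, lapply(f$geometry$coordinates,
                                  function(p) as.numeric(unlist(p)[1:2])))
      k <- nrow(cc) - 1L
      cls <- f$properties$road_class
      data.frame(seg_id = paste0("f", i, "_", seq_len(k)),
                 ax = cc[-nrow(cc), 1], ay = cc[-nrow(cc), 2],
                 bx = cc[-1, 1], by = cc[-1, 2],
                 length_m = NA_real_,
                 road_class = if (is.null(cls)) "other" else cls,
                 stringsAsFactors = FALSE)
    }))
  } else {
    segs <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  if (!is.null(class_aliases)) {
    hit <- segs$road_class %in% names(class_aliases)
    segs$road_class[hit] <- class_aliases[segs$road_class[hit]]
  }
  assert_projected(c(segs$ax, segs$bx), c(segs$ay, segs$by), "road network")
  road_segments(segs$ax, segs$ay, segs$bx, segs$by, segs$road_class,
                segs$length_m, segs$seg_id)
}

#' Read and build a road network from file
#'
#' @inheritParams read_segments
#' @param snap_tolerance endpoint merge tolerance in meters
#' @param quiet passed to [build_network()]
#' @return a `road_network`
#' @export
read_network <- function(path, snap_tolerance = 0.5, class_aliases = NULL,
                         quiet = FALSE) {
  build_network(read_segments(path, class_aliases), snap_tolerance,
                quiet = quiet)
}

ring_matrix <- function(ring)
  do.call(rbind, lapply(ring, function(p) as.numeric(unlist(p)[1:2])))

#' Read region polygons from GeoJSON
#'
#' Polygon and MultiPolygon features with a `region_id` property; interior
#' rings become holes.
#'
#' @param path file path
#' @return list of [region()] objects
#' @export
read_regions <- function(path) {
  features <- read_geojson_features(path)
  lapply(seq_along(features), function(i) {
    f <- features[[i]]
    id <- f$properties$region_id
    if (is.null(id)) id <- paste0("region", i)
    polys <- switch(f$geometry$type,
                    Polygon = list(f$geometry$coordinates),
                    MultiPolygon = f$geometry$coordinates,
                    stop("expected Polygon or MultiPolygon geometries",
                         call. = FALSE))
    parts <- lapply(polys, function(rings) {
      list(outer = ring_matrix(rings[[1]]),
           holes = lapply(rings[-1], ring_matrix))
    })
    out <- region(id, parts)
    allx <- unlist(lapply(out$parts, function(p) p$outer[, 1]))
    ally <- unlist(lapply(out$parts, function(p) p$outer[, 2]))
    assert_projected(allx, ally, paste0("region ", id))
    out
  })
}

fmt3 <- function(d) {
  num <- vapply(d, is.numeric, logical(1))
  d[num] <- lapply(d[num], function(z) formatC(z, format = "f", digits = 3))
  d
}

#' Write an access result as CSV
#'
#' Columns `block_id, facility_id, distance_km, time_min, population`,
#' numerics at 3 decimal places.
#'
#' @param result an `access_result`; @param path output path
#' @export
write_access <- function(result, path) {
  utils::write.csv(fmt3(as.data.frame(result)), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write a summary table as CSV (numerics at 3 decimal places)
#'
#' @param summary a data.frame; @param path output path
#' @export
write_summary <- function(summary, path) {
  utils::write.csv(fmt3(summary), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write demand blocks / facilities as CSV
#'
#' Full-precision coordinates so a written scenario reloads exactly.
#'
#' @param blocks a [demand_blocks()] data.frame; @param path output path
#' @export
write_blocks <- function(blocks, path) {
  utils::write.csv(blocks, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_blocks
#' @param facs a [facilities()] data.frame
#' @export
write_facilities <- function(facs, path) {
  utils::write.csv(facs, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a road network as an edge-list CSV
#'
#' Inverse of [read_segments()] for the CSV form.
#'
#' @param network a `road_network`; @param path output path
#' @export
write_network <- function(network, path) {
  el <- igraph::as_edgelist(network$graph, names = FALSE)
  g <- network$graph
  d <- data.frame(seg_id = igraph::E(g)$seg_id,
                  ax = network$coords[el[, 1], 1],
                  ay = network$coords[el[, 1], 2],
                  bx = network$coords[el[, 2], 1],
                  by = network$coords[el[, 2], 2],
                  length_m = igraph::E(g)$length_m,
                  road_class = igraph::E(g)$road_class,
                  stringsAsFactors = FALSE)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write regions as a GeoJSON FeatureCollection
#'
#' @param regions a [region()] or list of regions; @param path output path
#' @export
write_regions <- function(regions, path) {
  if (inherits(regions, "region")) regions <- list(regions)
  feat <- lapply(regions, function(r) {
    polys <- lapply(r$parts, function(p) {
      c(list(apply(p$outer, 1, function(v) as.list(v), simplify = FALSE)),
        lapply(p$holes, function(h)
          apply(h, 1, function(v) as.list(v), simplify = FALSE)))
    })
    list(type = "Feature",
         properties = list(region_id = r$region_id),
         geometry = list(type = "MultiPolygon", coordinates = polys))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feat),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
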