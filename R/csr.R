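#' Construct a planar region
#'
#' A region is one or more polygon parts in projected planar meters, each an
#' outer ring with optional holes. Used both to select the demand blocks and
#' facilities belonging to a target region and as the support of the CSR
#' relocation.
#'
#' @param region_id identifier
#' @param boundary an n x 2 coordinate matrix (single ring), or a list of
#'   parts where each part is either a ring matrix or
#'   `list(outer = <matrix>, holes = list(<matrix>, ...))`
#' @return object of class `region` with fields `region_id`, `parts`,
#'   `area_m2`, `bbox`
#' @export
region <- function(region_id, boundary) {
  if (is.matrix(boundary) || is.data.frame(boundary))
    boundary <- list(as.matrix(boundary))
  parts <- lapply(boundary, function(p) {
    if (is.matrix(p) || is.data.frame(p)) p <- list(outer = as.matrix(p), holes = list())
    if (is.null(p$holes)) p$holes <- list()
    p$outer <- close_ring(as.matrix(p$outer))
    p$holes <- lapply(p$holes, function(h) close_ring(as.matrix(h)))
    p
  })
  area <- sum(vapply(parts, function(p) {
    abs(pracma::polyarea(p$outer[, 1], p$outer[, 2])) -
      sum(vapply(p$holes, function(h) abs(pracma::polyarea(h[, 1], h[, 2])),
                 numeric(1)))
  }, numeric(1)))
  if (!is.finite(area) || area <= 0)
    stop("region polygon is degenerate (zero area)", call. = FALSE)
  allx <- unlist(lapply(parts, function(p) p$outer[, 1]))
  ally <- unlist(lapply(parts, function(p) p$outer[, 2]))
  structure(list(region_id = as.character(region_id), parts = parts,
                 area_m2 = area,
                 bbox = c(xmin = min(allx), xmax = max(allx),
                          ymin = min(ally), ymax = max(ally))),
            class = "region")
}

close_ring <- function(m) {
  if (nrow(m) < 3L) stop("polygon ring needs >= 3 vertices", call. = FALSE)
  if (!all(is.finite(m))) stop("non-finite polygon coordinates", call. = FALSE)
  if (any(m[1, ] != m[nrow(m), ])) m <- rbind(m, m[1, ])
  m
}

#' @export
print.region <- function(x, ...) {
  cat("region", x$region_id, ":", length(x$parts), "part(s), area",
      format(x$area_m2 / 1e6, digits = 6), "km^2\n")
  invisible(x)
}

#' Test whether points fall inside a region
#'
#' Inside any part's outer ring and inside none of its holes; ring
#' boundaries count as inside.
#'
#' @param reg a [region()]
#' @param x,y coordinate vectors
#' @return logical vector
#' @export
point_in_region <- function(reg, x, y) {
  inside <- rep(FALSE, length(x))
  for (p in reg$parts) {
    io <- pracma::inpolygon(x, y, p$outer[, 1], p$outer[, 2], boundary = TRUE)
    for (h in p$holes)
      io <- io & !pracma::inpolygon(x, y, h[, 1], h[, 2], boundary = FALSE)
    inside <- inside | io
  }
  inside
}

#' Sample points uniformly over a region (CSR draw)
#'
#' Draws `n` points i.i.d. uniform over the region polygon by rejection
#' sampling from its bounding box. With the facility count fixed by
#' conditioning, this is exactly the conditional form of a homogeneous
#' Poisson process (complete spatial randomness) on the region.
#' Reproducible under `set.seed()`.
#'
#' @param reg a [region()]
#' @param n number of points (>= 0)
#' @return n x 2 matrix of coordinates
#' @export
sample_csr_points <- function(reg, n) {
  if (n < 0) stop("n must be >= 0", call. = FALSE)
  out <- matrix(numeric(0), 0, 2)
  if (n == 0L) return(out)
  bb <- reg$bbox
  frac <- reg$area_m2 / ((bb["xmax"] - bb["xmin"]) * (bb["ymax"] - bb["ymin"]))
  for (iter in seq_len(10000L)) {
    m <- ceiling((n - nrow(out)) / max(frac, 1e-6)) + 8L
    cand <- cbind(stats::runif(m, bb["xmin"], bb["xmax"]),
                  stats::runif(m, bb["ymin"], bb["ymax"]))
    keep <- point_in_region(reg, cand[, 1], cand[, 2])
    out <- rbind(out, cand[keep, , drop = FALSE])
    if (nrow(out) >= n) return(out[seq_len(n), , drop = FALSE])
  }
  stop("rejection sampling failed to fill the region; degenerate polygon?",
       call. = FALSE)
}

#' Monte Carlo configuration for the CSR standardization
#'
#' @param n_reps number of CSR relocations (default 99, so the expectation
#'   averages 99 simulated values together with the observed one)
#' @param seed integer seed, or `NULL` to use the current RNG state
#' @param weight nearest-facility weight, `"distance"` (default) or `"time"`
#' @param snap_relocated snap relocated facilities to the nearest network
#'   node before routing (default `TRUE`; in network mode routing always
#'   goes through the snapped node, the flag is recorded as metadata)
#' @param mode `"network"` (default) or `"euclidean"` for fast exploration
#' @return list of class `csr_config`
#' @export
csr_config <- function(n_reps = 99, seed = NULL, weight = "distance",
                       snap_relocated = TRUE, mode = "network") {
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  structure(list(n_reps = as.integer(n_reps), seed = seed,
                 weight = match.arg(weight, c("distance", "time")),
                 snap_relocated = isTRUE(snap_relocated),
                 mode = match.arg(mode, c("network", "euclidean"))),
            class = "csr_config")
}

# Independent per-region RNG stream: offset the base seed by a hash of the
# region id, kept within 32-bit integer range.
region_seed <- function(seed, region_id) {
  h <- sum(utf8ToInt(as.character(region_id)) * seq_along(utf8ToInt(as.character(region_id))))
  as.integer((as.numeric(seed) + 7919 * h) %% .Machine$integer.max)
}

#' Expected inequality under CSR relocation, and the standardized ratio
#'
#' Implements the Monte Carlo standardization for one target region:
#' facilities are split into inside/outside the region; in each replicate
#' the inside facilities are relocated to a fresh uniform (CSR) draw over
#' the region while outside facilities stay fixed; every block inside the
#' region is reassigned to its nearest facility among all of them, and the
#' relative mean difference D of the resulting travel times is recorded.
#' The expectation `D_bar` is the mean of the `n_reps` simulated D values
#' together with the observed D, and the standardized ratio is
#' `R = D_observed / D_bar`.
#'
#' Only blocks inside the region enter D; facilities outside remain
#' candidates throughout, exactly as in the observed assignment.
#'
#' @param network a [build_network()] result (`NULL` allowed in euclidean mode)
#' @param blocks [demand_blocks()]; restricted internally to the region
#' @param facs [facilities()]; all are candidates, inside ones are relocated
#' @param reg the target [region()]
#' @param speeds a [speed_table()]
#' @param config a [csr_config()]
#' @return object of class `csr_result`: `region_id, D_observed, D_sim,
#'   D_bar, ratio, mean_time_min, n_reps, seed, weight, mode,
#'   snap_relocated, n_blocks, n_inside_facilities`
#' @export
simulate_expected_D <- function(network, blocks, facs, reg,
                                speeds = speed_table(),
                                config = csr_config()) {
  stopifnot(inherits(reg, "region"), inherits(config, "csr_config"))
  inb <- point_in_region(reg, blocks$x, blocks$y)
  blocks_in <- blocks[inb & blocks$population > 0, , drop = FALSE]
  if (nrow(blocks_in) == 0L)
    stop("no populated blocks inside region ", reg$region_id, call. = FALSE)
  inf <- point_in_region(reg, facs$x, facs$y)
  if (!any(inf))
    stop("no facilities inside region ", reg$region_id, call. = FALSE)
  fac_in <- facs[inf, , drop = FALSE]
  fac_out <- facs[!inf, , drop = FALSE]

  obs <- assign_nearest(network, blocks_in, facs, weight = config$weight,
                        speeds = speeds, mode = config$mode, quiet = TRUE)
  D_obs <- relative_mean_difference(obs$time_min, obs$population)

  if (!is.null(config$seed))
    set.seed(region_seed(config$seed, reg$region_id))
  D_sim <- numeric(config$n_reps)
  for (r in seq_len(config$n_reps)) {
    pts <- sample_csr_points(reg, nrow(fac_in))
    fac_r <- fac_in
    fac_r$x <- pts[, 1]; fac_r$y <- pts[, 2]
    cand <- rbind(fac_r, fac_out)
    sim <- tryCatch(
      assign_nearest(network, blocks_in, cand, weight = config$weight,
                     speeds = speeds, mode = config$mode, quiet = TRUE),
      error = function(e) stop("replicate ", r, ": ", conditionMessage(e),
                               call. = FALSE))
    D_sim[r] <- tryCatch(
      relative_mean_difference(sim$time_min, sim$population),
      error = function(e) stop("replicate ", r, ": ", conditionMessage(e),
                               call. = FALSE))
  }
  D_bar <- mean(c(D_sim, D_obs))
  structure(list(region_id = reg$region_id,
                 D_observed = D_obs, D_sim = D_sim, D_bar = D_bar,
                 ratio = standardized_ratio(D_obs, D_bar),
                 mean_time_min = mean_access_time(obs),
                 n_reps = config$n_reps, seed = config$seed,
                 weight = config$weight, mode = config$mode,
                 snap_relocated = config$snap_relocated,
                 n_blocks = nrow(blocks_in),
                 n_inside_facilities = nrow(fac_in)),
            class = "csr_result")
}

#' @export
print.csr_result <- function(x, ...) {
  cat(sprintf("region %s: D = %.3f, D_bar = %.3f (%d reps), R = %.3f\n",
              x$region_id, x$D_observed, x$D_bar, x$n_reps, x$ratio))
  invisible(x)
}

#' Standardized inequality ratio R = D / D_bar
#'
#' The observed relative mean difference divided by its CSR expectation.
#' R near 1 means the observed facility layout produces no more inequality
#' than a spatially random one; large R flags regions where the layout
#' concentrates access.
#'
#' @param D_observed observed D
#' @param D_bar CSR expectation of D (must be > 0)
#' @return the ratio
#' @examples
#' standardized_ratio(1.077, 0.341)
#' @export
standardized_ratio <- function(D_observed, D_bar) {
  if (!is.finite(D_bar) || D_bar <= 0) stop("D_bar must be > 0", call. = FALSE)
  D_observed / D_bar
}

#' Rank regions by raw and standardized inequality
#'
#' Ascending ranks (1 = least inequality) by the standardized ratio R and,
#' for comparison, by raw D; ties share the lower rank.
#'
#' @param results list of `csr_result` objects, or a data.frame with at
#'   least columns `region_id`, `D` and `ratio` (e.g. published area
#'   summaries)
#' @return data.frame with the input columns plus `rank_D` and `rank_ratio`
#' @export
rank_regions <- function(results) {
  if (inherits(results, "csr_result")) results <- list(results)
  if (is.data.frame(results)) {
    df <- results
    if (!all(c("region_id", "D", "ratio") %in% names(df)))
      stop("data.frame input needs columns region_id, D, ratio", call. = FALSE)
  } else {
    if (length(results) == 0L) stop("no results to rank", call. = FALSE)
    df <- data.frame(
      region_id = vapply(results, `[[`, character(1), "region_id"),
      mean_time_min = vapply(results, `[[`, numeric(1), "mean_time_min"),
      D = vapply(results, `[[`, numeric(1), "D_observed"),
      D_bar = vapply(results, `[[`, numeric(1), "D_bar"),
      ratio = vapply(results, `[[`, numeric(1), "ratio"),
      n_reps = vapply(results, `[[`, integer(1), "n_reps"),
      stringsAsFactors = FALSE)
  }
  df$rank_D <- rank(df$D, ties.method = "min")
  df$rank_ratio <- rank(df$ratio, ties.method = "min")
  df
}
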