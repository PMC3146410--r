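#' Regular grid road network
#'
#' An `nx` x `ny` lattice of nodes at `spacing` meters, joined by
#' horizontal and vertical segments. `class_rule`, if given, is a function
#' receiving the segment data.frame (columns `ax, ay, bx, by`) and
#' returning a road class per segment; by default all segments are class
#' `"other"`.
#'
#' @param nx,ny lattice dimensions (each >= 2)
#' @param spacing segment length in meters (> 0)
#' @param class_rule optional function assigning road classes
#' @param origin lower-left corner, numeric length-2 (default `c(0, 0)`)
#' @param quiet passed to [build_network()]
#' @return a `road_network`
#' @examples
#' make_grid_network(5, 5, 1000)   # 25 nodes, 40 edges
#' @export
make_grid_network <- function(nx, ny, spacing, class_rule = NULL,
                              origin = c(0, 0), quiet = TRUE) {
  if (nx < 2 || ny < 2) stop("nx and ny must be >= 2", call. = FALSE)
  if (spacing <= 0) stop("spacing must be > 0", call. = FALSE)
  xs <- origin[1] + (seq_len(nx) - 1) * spacing
  ys <- origin[2] + (seq_len(ny) - 1) * spacing
  # horizontal segments
  h <- expand.grid(i = seq_len(nx - 1), j = seq_len(ny))
  # vertical segments
  v <- expand.grid(i = seq_len(nx), j = seq_len(ny - 1))
  seg <- data.frame(
    ax = c(xs[h$i], xs[v$i]), ay = c(ys[h$j], ys[v$j]),
    bx = c(xs[h$i + 1], xs[v$i]), by = c(ys[h$j], ys[v$j + 1]))
  cls <- if (is.null(class_rule)) "other" else class_rule(seg)
  build_network(road_segments(seg$ax, seg$ay, seg$bx, seg$by, road_class = cls),
                snap_tolerance = 0, quiet = quiet)
}

#' Scenario specification for the synthetic generator
#'
#' Describes a self-contained study scenario: a square region, a grid road
#' network spanning it, demand blocks with skewed (log-normal) populations,
#' and a facility layout in one of four arrangements mirroring the
#' canonical point-pattern archetypes: `regular` (facilities on a centered
#' lattice), `clustered` (blocks and facilities around Gaussian cluster
#' centers), `circular` (blocks on a ring, facility at the center — the
#' optimal-location limit where every block is equidistant), and `random`
#' (facilities are themselves a CSR draw, for null-calibration checks).
#'
#' @param arrangement one of `"regular", "clustered", "circular", "random"`
#' @param n_blocks,n_facilities counts (>= 1)
#' @param extent side of the square region in meters (default 10000)
#' @param pop_meanlog,pop_sdlog log-normal parameters for block populations
#'   (defaults 3 and 1 give a right-skewed count distribution with median
#'   about 20 children per block, like census blocks)
#' @param grid_n nodes per side of the road grid (default 11)
#' @param n_clusters Gaussian cluster count for `clustered` (default 3)
#' @param seed integer seed making the scenario reproducible
#' @return list of class `scenario_spec`
#' @export
scenario_spec <- function(arrangement = c("regular", "clustered", "circular",
                                          "random"),
                          n_blocks = 100, n_facilities = 5, extent = 10000,
                          pop_meanlog = 3, pop_sdlog = 1,
                          grid_n = 11, n_clusters = 3, seed = 1) {
  arrangement <- match.arg(arrangement)
  if (n_blocks < 1 || n_facilities < 1) stop("counts must be >= 1", call. = FALSE)
  if (extent <= 0) stop("extent must be > 0", call. = FALSE)
  if (pop_sdlog < 0) stop("pop_sdlog must be >= 0", call. = FALSE)
  if (grid_n < 2) stop("grid_n must be >= 2", call. = FALSE)
  structure(list(arrangement = arrangement, n_blocks = n_blocks,
                 n_facilities = n_facilities, extent = extent,
                 pop_meanlog = pop_meanlog, pop_sdlog = pop_sdlog,
                 grid_n = grid_n, n_clusters = n_clusters, seed = seed),
            class = "scenario_spec")
}

clamp <- function(z, lo, hi) pmin(pmax(z, lo), hi)

#' Generate a synthetic study scenario
#'
#' Fully reproducible from the seed in the spec. All generated geometry
#' lies inside the declared square region; block populations are integers
#' of at least 1.
#'
#' @param spec a [scenario_spec()]
#' @return list with elements `region`, `network`, `blocks`, `facilities`,
#'   `spec`
#' @export
make_scenario <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(spec$seed)
  L <- spec$extent
  reg <- region("R1", rbind(c(0, 0), c(L, 0), c(L, L), c(0, L)))
  # grid network spanning the region, principal roads on the middle row/column
  sp_ <- L / (spec$grid_n - 1)
  mid <- L / 2
  rule <- function(seg) {
    onmid <- (seg$ay == seg$by & abs(seg$ay - mid) < sp_ / 2) |
             (seg$ax == seg$bx & abs(seg$ax - mid) < sp_ / 2)
    ifelse(onmid, "national_or_principal", "other")
  }
  net <- make_grid_network(spec$grid_n, spec$grid_n, sp_, class_rule = rule)

  eps <- L * 1e-6
  nb <- spec$n_blocks; nf <- spec$n_facilities
  if (spec$arrangement == "circular") {
    theta <- 2 * pi * (seq_len(nb) - 1) / nb
    r <- L / 3
    bx <- mid + r * cos(theta); by <- mid + r * sin(theta)
    fx <- rep(mid, nf); fy <- rep(mid, nf)
  } else if (spec$arrangement == "clustered") {
    k <- max(1L, spec$n_clusters)
    cx <- stats::runif(k, L / 4, 3 * L / 4)
    cy <- stats::runif(k, L / 4, 3 * L / 4)
    sd_ <- L / 15
    ib <- sample.int(k, nb, replace = TRUE)
    bx <- clamp(stats::rnorm(nb, cx[ib], sd_), eps, L - eps)
    by <- clamp(stats::rnorm(nb, cy[ib], sd_), eps, L - eps)
    if_ <- sample.int(k, nf, replace = TRUE)
    fx <- clamp(stats::rnorm(nf, cx[if_], sd_), eps, L - eps)
    fy <- clamp(stats::rnorm(nf, cy[if_], sd_), eps, L - eps)
  } else {
    bx <- stats::runif(nb, 0, L); by <- stats::runif(nb, 0, L)
    if (spec$arrangement == "regular") {
      side <- ceiling(sqrt(nf))
      gx <- (seq_len(side) - 0.5) * L / side
      gg <- expand.grid(x = gx, y = gx)[seq_len(nf), ]
      fx <- gg$x; fy <- gg$y
    } else {  # random: facilities are a CSR draw
      fpts <- sample_csr_points(reg, nf)
      fx <- fpts[, 1]; fy <- fpts[, 2]
    }
  }
  pop <- pmax(1L, as.integer(round(stats::rlnorm(nb, spec$pop_meanlog,
                                                 spec$pop_sdlog))))
  list(region = reg,
       network = net,
       blocks = demand_blocks(sprintf("b%03d", seq_len(nb)), bx, by, pop),
       facilities = facilities(sprintf("f%03d", seq_len(nf)), fx, fy,
                               region_id = reg$region_id),
       spec = spec)
}
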