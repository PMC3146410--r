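test_that("segment travel time follows the road-class speed model", {
  expect_equal(segment_travel_time(100, 60), 0.1)      # 6 seconds
  expect_equal(segment_travel_time(0, 50), 0)
  expect_equal(segment_travel_time(80000, 80), 60)     # one hour at the limit
  expect_equal(segment_travel_time(1000, 40), 1.5)
  expect_error(segment_travel_time(100, 0), "speed")
  expect_error(segment_travel_time(-1, 60), "length")
})

test_that("speed table defaults match the legal limits and reject bad speeds", {
  s <- speed_table()
  expect_equal(unclass(s), c(toll = 80, national_or_principal = 60, other = 40))
  expect_error(speed_table(other = -10), "speeds")
  expect_error(road_segments(0, 0, 1, 1, road_class = "motorway"), "road_class")
})

test_that("build_network merges endpoints and labels components", {
  sq <- road_segments(ax = c(0, 1000, 1000, 0), ay = c(0, 0, 1000, 1000),
                      bx = c(1000, 1000, 0, 0), by = c(0, 1000, 1000, 0))
  net <- build_network(sq, snap_tolerance = 0, quiet = TRUE)
  expect_equal(igraph::vcount(net$graph), 4)
  expect_equal(igraph::ecount(net$graph), 4)
  expect_equal(net$n_components, 1)

  two <- road_segments(ax = c(0, 5000), ay = c(0, 5000),
                       bx = c(1000, 6000), by = c(0, 5000))
  expect_equal(build_network(two, quiet = TRUE)$n_components, 2)

  # jittered endpoints within tolerance are fused into one intersection
  jit <- road_segments(ax = c(0, 1000.3), ay = c(0, 0.2),
                       bx = c(1000, 2000), by = c(0, 0))
  expect_equal(build_network(jit, snap_tolerance = 0.5, quiet = TRUE)$n_components, 1)
  expect_equal(build_network(jit, snap_tolerance = 0, quiet = TRUE)$n_components, 2)

  expect_error(build_network(data.frame()), "empty")
})

test_that("grid network node and edge counts match the lattice topology", {
  for (dims in list(c(5, 5), c(10, 20), c(2, 2))) {
    net <- make_grid_network(dims[1], dims[2], 500)
    expect_equal(igraph::vcount(net$graph), dims[1] * dims[2])
    expect_equal(igraph::ecount(net$graph),
                 (dims[1] - 1) * dims[2] + dims[1] * (dims[2] - 1))
    expect_equal(net$n_components, 1)
  }
})

test_that("shortest path minimizes the chosen weight and reports both totals", {
  net <- triangle_net()
  a <- snap_point(net, c(3000, 0)); b <- snap_point(net, c(0, 4000))
  sp <- shortest_path(net, a, b, weight = "distance")
  expect_equal(sp$distance_km, 5)                 # hypotenuse, not 3 + 4
  expect_equal(length(sp$path), 2)
  expect_equal(sp$time_min, 5 / 40 * 60)

  same <- shortest_path(net, a, a)
  expect_equal(same$distance_km, 0)
  expect_equal(same$time_min, 0)
  expect_equal(same$path, a)
})

test_that("a longer toll route can win on time but not on distance", {
  # A--T--B is 8 km toll (6.0 min); A--O--B is 7 km other (10.5 min)
  seg <- road_segments(ax = c(0, 4000, 0, 3500), ay = c(0, 1000, 0, -1000),
                       bx = c(4000, 8000, 3500, 8000), by = c(1000, 0, -1000, 0),
                       road_class = c("toll", "toll", "other", "other"),
                       length_m = c(4000, 4000, 3500, 3500))
  net <- build_network(seg, snap_tolerance = 0, quiet = TRUE)
  a <- snap_point(net, c(0, 0)); b <- snap_point(net, c(8000, 0))
  by_time <- shortest_path(net, a, b, weight = "time")
  by_dist <- shortest_path(net, a, b, weight = "distance")
  expect_equal(by_time$distance_km, 8)
  expect_equal(by_time$time_min, 6)
  expect_equal(by_dist$distance_km, 7)
  expect_equal(by_dist$time_min, 10.5)
})

test_that("routing across components fails with a clear error", {
  two <- road_segments(ax = c(0, 5000), ay = c(0, 5000),
                       bx = c(1000, 6000), by = c(0, 5000))
  net <- build_network(two, quiet = TRUE)
  a <- snap_point(net, c(0, 0))
  b <- snap_point(net, c(5000, 5000))
  expect_error(shortest_path(net, a, b), "different network components")
})

test_that("snap_point is the brute-force nearest node with low-id ties", {
  net <- make_grid_network(6, 6, 1000)
  expect_equal(snap_point(net, net$coords[17, ]), 17)
  # equidistant between two nodes -> lowest index
  mid <- (net$coords[1, ] + net$coords[2, ]) / 2
  expect_equal(snap_point(net, mid), min(1:2))
  set.seed(11)
  for (i in 1:20) {
    p <- runif(2, -500, 5500)
    d2 <- (net$coords[, 1] - p[1])^2 + (net$coords[, 2] - p[2])^2
    expect_equal(snap_point(net, p), which.min(d2))
  }
})

test_that("network metric properties hold on a synthetic grid", {
  net <- make_grid_network(5, 4, 700, class_rule = function(s)
    ifelse(s$ay == s$by, "national_or_principal", "other"))
  nv <- igraph::vcount(net$graph)
  set.seed(3)
  trips <- matrix(sample(nv, 30, replace = TRUE), ncol = 3)
  d <- function(u, v) shortest_path(net, u, v)$distance_km
  for (k in seq_len(nrow(trips))) {
    tr <- trips[k, ]
    expect_lte(d(tr[1], tr[3]), d(tr[1], tr[2]) + d(tr[2], tr[3]) + 1e-9)
  }
  # scaling all speeds by c divides every time by c; distances untouched
  s1 <- speed_table(); s3 <- speed_table(240, 180, 120)
  for (k in 1:5) {
    u <- trips[k, 1]; v <- trips[k, 2]
    p1 <- shortest_path(net, u, v, weight = "time", speeds = s1)
    p3 <- shortest_path(net, u, v, weight = "time", speeds = s3)
    expect_equal(p1$time_min, 3 * p3$time_min)
    expect_equal(p1$distance_km, p3$distance_km)
    # distance-weighted routing ignores the speed table entirely: the
    # minimized distance, and the time up to the uniform speed rescaling,
    # are unchanged (tied routes equal on both metrics may swap)
    d1 <- shortest_path(net, u, v, weight = "distance", speeds = s1)
    d3 <- shortest_path(net, u, v, weight = "distance", speeds = s3)
    expect_identical(d1$distance_km, d3$distance_km)
    expect_equal(d1$time_min, 3 * d3$time_min)
  }
})

test_that("on a uniform-class network time and distance paths coincide", {
  net <- make_grid_network(6, 6, 800)
  set.seed(4)
  for (k in 1:10) {
    uv <- sample(igraph::vcount(net$graph), 2)
    pt <- shortest_path(net, uv[1], uv[2], weight = "time")
    pd <- shortest_path(net, uv[1], uv[2], weight = "distance")
    expect_equal(pt$distance_km, pd$distance_km)
    expect_equal(pt$time_min, pd$time_min)
  }
})
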