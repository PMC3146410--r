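# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's fast code paths: D by the O(n^2) double sum, nearest
# assignment by exhaustive per-pair shortest paths.

brute_D <- function(x, w = rep(1, length(x))) {
  W <- sum(w)
  xbar <- sum(w * x) / W
  md <- 0
  for (i in seq_along(x))
    for (j in seq_along(x))
      md <- md + w[i] * w[j] * abs(x[i] - x[j])
  (md / W^2) / xbar
}

brute_nearest <- function(network, blocks, facs, weight = "distance",
                          speeds = speed_table()) {
  facs <- facs[order(facs$facility_id), ]
  out <- lapply(seq_len(nrow(blocks)), function(i) {
    bn <- snap_point(network, c(blocks$x[i], blocks$y[i]))
    best <- NULL; bestw <- Inf
    for (j in seq_len(nrow(facs))) {
      fn <- snap_point(network, c(facs$x[j], facs$y[j]))
      sp <- shortest_path(network, bn, fn, weight = weight, speeds = speeds)
      wv <- if (weight == "distance") sp$distance_km else sp$time_min
      if (wv < bestw) { bestw <- wv; best <- c(j, sp$distance_km, sp$time_min) }
    }
    data.frame(block_id = blocks$block_id[i], facility_id = facs$facility_id[best[1]],
               distance_km = best[2], time_min = best[3],
               population = blocks$population[i], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# small fixture networks -----------------------------------------------------

# right triangle with legs 3, 4 and hypotenuse 5 (kilometers as meters x1000)
triangle_net <- function(class = "other") {
  seg <- road_segments(ax = c(0, 0, 3000), ay = c(0, 0, 0),
                       bx = c(3000, 0, 0), by = c(0, 4000, 4000),
                       road_class = class)
  build_network(seg, snap_tolerance = 0, quiet = TRUE)
}

# straight west-east road with nodes every `spacing` meters
line_net <- function(n_nodes, spacing = 1000, class = "other") {
  xs <- (seq_len(n_nodes) - 1) * spacing
  seg <- road_segments(ax = xs[-n_nodes], ay = 0, bx = xs[-1], by = 0,
                       road_class = class)
  build_network(seg, snap_tolerance = 0, quiet = TRUE)
}

random_weighted_sample <- function(n) {
  list(x = stats::rexp(n) + stats::runif(n, 0, 0.2),
       w = sample(1:9, n, replace = TRUE))
}
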