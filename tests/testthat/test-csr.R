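unit_square <- function(id = "U", side = 1000)
  region(id, rbind(c(0, 0), c(side, 0), c(side, side), c(0, side)))

test_that("region area and membership work for simple and holed polygons", {
  sq <- unit_square(side = 2000)
  expect_equal(sq$area_m2, 4e6)
  expect_true(point_in_region(sq, 1000, 1000))
  expect_false(point_in_region(sq, -1, 1000))
  holed <- region("H", list(list(
    outer = rbind(c(0, 0), c(1000, 0), c(1000, 1000), c(0, 1000)),
    holes = list(rbind(c(400, 400), c(600, 400), c(600, 600), c(400, 600))))))
  expect_equal(holed$area_m2, 1e6 - 200^2)
  expect_false(point_in_region(holed, 500, 500))
  expect_true(point_in_region(holed, 100, 100))
  expect_error(region("bad", rbind(c(0, 0), c(1, 1), c(2, 2))), "degenerate")
})

test_that("CSR sampler is uniform on its support and empty for n = 0", {
  sq <- unit_square()
  expect_equal(nrow(sample_csr_points(sq, 0)), 0)
  set.seed(42)
  pts <- sample_csr_points(sq, 10000)
  expect_equal(nrow(pts), 10000)
  expect_true(all(point_in_region(sq, pts[, 1], pts[, 2])))
  # quadrat chi-square over a 4x4 equal-area grid
  cell <- pmin(floor(pts[, 1] / 250), 3) + 4 * pmin(floor(pts[, 2] / 250), 3)
  counts <- tabulate(cell + 1, nbins = 16)
  chi2 <- sum((counts - 625)^2 / 625)
  expect_lt(chi2, qchisq(0.999, df = 15))
})

test_that("CSR samples respect a non-convex (L-shaped) support", {
  L <- region("L", rbind(c(0, 0), c(1000, 0), c(1000, 500),
                         c(500, 500), c(500, 1000), c(0, 1000)))
  expect_equal(L$area_m2, 750000)
  set.seed(7)
  pts <- sample_csr_points(L, 2000)
  # excluded quadrant: x > 500 & y > 500
  expect_equal(sum(pts[, 1] > 500 & pts[, 2] > 500), 0)
  expect_true(all(point_in_region(L, pts[, 1], pts[, 2])))
})

test_that("standardized ratio is plain division with a guarded denominator", {
  expect_equal(standardized_ratio(0.84, 0.84), 1)
  expect_equal(standardized_ratio(1.5, 0.5), 3)
  expect_error(standardized_ratio(1, 0), "D_bar")
})

test_that("CSR simulation is reproducible and conserves facility counts", {
  sc <- make_scenario(scenario_spec("clustered", n_blocks = 40,
                                    n_facilities = 6, seed = 21))
  cfg <- csr_config(n_reps = 7, seed = 99)
  r1 <- simulate_expected_D(sc$network, sc$blocks, sc$facilities, sc$region,
                            config = cfg)
  r2 <- simulate_expected_D(sc$network, sc$blocks, sc$facilities, sc$region,
                            config = cfg)
  expect_identical(r1$D_sim, r2$D_sim)
  expect_identical(r1$ratio, r2$ratio)
  expect_equal(length(r1$D_sim), 7)
  expect_equal(r1$D_bar, mean(c(r1$D_sim, r1$D_observed)))
  expect_equal(r1$n_inside_facilities, 6)
  # a different seed moves the simulated values
  r3 <- simulate_expected_D(sc$network, sc$blocks, sc$facilities, sc$region,
                            config = csr_config(n_reps = 7, seed = 100))
  expect_false(identical(r1$D_sim, r3$D_sim))
})

test_that("outside facilities stay fixed and blocks outside are excluded", {
  # region covers the left half of a line network; one facility far right
  net <- line_net(11, spacing = 1000)
  reg <- region("left", rbind(c(-100, -100), c(5100, -100),
                              c(5100, 100), c(-100, 100)))
  blocks <- demand_blocks(paste0("b", 1:6),
                          x = c(0, 1000, 2000, 3000, 4000, 9000),
                          y = 0, population = c(3, 1, 4, 1, 5, 100))
  facs <- facilities(c("fin", "fout"), x = c(2000, 10000), y = c(0, 0))
  res <- simulate_expected_D(net, blocks, facs, reg,
                             config = csr_config(n_reps = 5, seed = 1))
  expect_equal(res$n_blocks, 5)                # b6 is outside the region
  expect_equal(res$n_inside_facilities, 1)
  # the observed D must not be influenced by the outside block's population:
  obs <- assign_nearest(net, blocks[1:5, ], facs, quiet = TRUE)
  expect_equal(res$D_observed,
               relative_mean_difference(obs$time_min, obs$population))
})

test_that("scaling all speeds leaves D, simulated Ds and R unchanged", {
  sc <- make_scenario(scenario_spec("clustered", n_blocks = 30,
                                    n_facilities = 5, seed = 31))
  cfg <- csr_config(n_reps = 5, seed = 17)
  r1 <- simulate_expected_D(sc$network, sc$blocks, sc$facilities, sc$region,
                            speeds = speed_table(), config = cfg)
  r2 <- simulate_expected_D(sc$network, sc$blocks, sc$facilities, sc$region,
                            speeds = speed_table(160, 120, 80), config = cfg)
  expect_identical(r1$D_observed, r2$D_observed)
  expect_identical(r1$D_sim, r2$D_sim)
  expect_identical(r1$ratio, r2$ratio)
})

test_that("ranking matches an independent sort and shares tied ranks", {
  fake <- function(id, D, ratio) structure(
    list(region_id = id, D_observed = D, D_sim = numeric(0), D_bar = D / ratio,
         ratio = ratio, mean_time_min = 1, n_reps = 0L, seed = NULL,
         weight = "distance", mode = "network", snap_relocated = TRUE,
         n_blocks = 1L, n_inside_facilities = 1L), class = "csr_result")
  res <- list(fake("a", 1.2, 2.0), fake("b", 0.8, 3.5), fake("c", 1.0, 2.0))
  rk <- rank_regions(res)
  expect_equal(rk$rank_D, c(3, 1, 2))
  expect_equal(rk$rank_ratio, c(1, 3, 1))      # ties share the lower rank
  expect_equal(rk$rank_ratio, rank(rk$ratio, ties.method = "min"))
  expect_equal(rank_regions(res[2])$rank_D, 1)
  set.seed(5)
  rnd <- lapply(1:8, function(i) fake(paste0("r", i), runif(1, 0.5, 1.5),
                                      runif(1, 1, 5)))
  rk2 <- rank_regions(rnd)
  expect_equal(order(rk2$ratio), order(rk2$rank_ratio))
})
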