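# Gridding: projection, cell assignment, demand filtering, distances.

make_test_grid <- function(n = 10, origin = c(-74, 40.7), ref = 40.7) {
  grid_spec(100, n_cols = n, n_rows = n, origin = origin,
            reference_latitude = ref, mode = "lonlat")
}

test_that("equirectangular projection matches its closed form", {
  grid <- make_test_grid()
  expect_equal(project_point(cbind(-74, 40.7), grid), cbind(x = 0, y = 0))
  # 0.001 deg latitude -> 111.32 m
  expect_equal(unname(project_point(cbind(-74, 40.701), grid)[, "y"]), 111.32,
               tolerance = 1e-9)
  # 0.001 deg longitude at reference latitude 40.7
  expect_equal(unname(project_point(cbind(-73.999, 40.7), grid)[, "x"]),
               111320 * cos(40.7 * pi / 180) * 0.001, tolerance = 1e-9)
  expect_equal(unname(project_point(cbind(-73.999, 40.7), grid)[, "x"]),
               84.40, tolerance = 1e-3)
})

test_that("non-finite points are flagged, not fatal", {
  grid <- make_test_grid()
  xy <- project_point(cbind(c(-74, NA), c(40.7, 40.7)), grid)
  z <- assign_zone(xy, grid)
  expect_true(z$in_bounds[1])
  expect_false(z$in_bounds[2])
})

test_that("cell assignment follows the half-open convention", {
  grid <- grid_spec(100, n_cols = 5, n_rows = 5, mode = "planar")
  z <- assign_zone(rbind(c(0, 0), c(99.999, 0), c(100, 0), c(130, 250),
                         c(-1, 0), c(0, 500)), grid)
  expect_equal(z$row[1:4], c(0L, 0L, 0L, 2L))
  expect_equal(z$col[1:4], c(0L, 0L, 1L, 1L))
  expect_false(z$in_bounds[5])  # negative x
  expect_false(z$in_bounds[6])  # y == n*L is outside the half-open grid
})

test_that("endpoint counts conserve in-bounds trips and ignore order", {
  grid <- grid_spec(100, n_cols = 3, n_rows = 3, mode = "planar")
  # 6 trips over 3 cells, plus one with an out-of-grid destination
  px <- c(50, 50, 150, 150, 250, 50, 50)
  py <- c(50, 50, 50, 50, 50, 50, 50)
  dx <- c(150, 150, 250, 50, 50, 50, 950)
  dy <- c(50, 50, 50, 50, 50, 50, 50)
  trips <- data.frame(pickup_x = px, pickup_y = py, dropoff_x = dx, dropoff_y = dy)
  attr(trips, "mode") <- "planar"
  counts <- count_endpoints(trips, grid)
  expect_equal(counts$n_in_bounds, 6)
  expect_equal(counts$n_excluded, 1)
  expect_equal(sum(counts$origins), sum(counts$destinations))
  # hand enumeration: origins cell(0,0) x3, (0,1) x2, (0,2) x1
  expect_equal(counts$origins[1, ], c(3, 2, 1))
  expect_equal(counts$destinations[1, ], c(3, 2, 1))
  # permuting the records changes nothing
  perm <- sample(nrow(trips))
  counts2 <- count_endpoints(trips[perm, ], grid)
  expect_identical(counts, counts2)
})

test_that("high-demand selection applies the AND rule at the boundary", {
  grid <- grid_spec(100, n_cols = 2, n_rows = 1, mode = "planar")
  counts <- list(origins = matrix(c(1000, 1000), 1),
                 destinations = matrix(c(1000, 999), 1))
  zs <- select_high_demand(counts, grid, M = 1000)
  expect_equal(nrow(zs), 1)          # second zone dropped: arrivals 999
  expect_equal(zs$col, 0L)
  expect_error(select_high_demand(counts, grid, M = 2000), "threshold")
})

test_that("raising M never grows the zone set", {
  layout <- make_zone_layout("uniform-random", 40, c(1, 1), seed = 6)
  trips <- generate_trips(layout, n_trips = 5000, seed = 6, jitter = FALSE)
  grid <- grid_spec(100, n_cols = 11, n_rows = 11, mode = "planar")
  counts <- count_endpoints(trips, grid)
  sizes <- vapply(c(1, 10, 50, 100), function(M)
    tryCatch(nrow(select_high_demand(counts, grid, M)),
             error = function(e) 0L), 0L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("trip restriction keeps both-endpoint matches and reports the fraction", {
  grid <- grid_spec(100, n_cols = 3, n_rows = 1, mode = "planar")
  counts <- list(origins = matrix(c(5, 5, 1), 1),
                 destinations = matrix(c(5, 5, 1), 1))
  zs <- select_high_demand(counts, grid, M = 2)  # zones: cells 0 and 1
  # 10 trips: 6 stay within kept cells, 4 touch the dropped cell
  px <- c(50, 50, 150, 150, 50, 150, 50, 250, 50, 250)
  dx <- c(50, 150, 50, 150, 50, 150, 250, 50, 250, 250)
  trips <- data.frame(pickup_x = px, pickup_y = rep(50, 10),
                      dropoff_x = dx, dropoff_y = rep(50, 10))
  attr(trips, "mode") <- "planar"
  res <- restrict_trips(trips, zs)
  expect_equal(nrow(res$trips), 6)
  expect_equal(res$fraction, 0.6)
  expect_true(all(res$trips$origin_zone %in% zs$zone_id))
})

test_that("haversine distances agree with known references", {
  zones <- data.frame(lon = c(-73.9855, -73.9855), lat = c(40.7580, 40.7680))
  D <- zone_distances(zones)
  # 0.01 deg latitude: exact closed form on the fixed-radius sphere, and
  # ~1.1132 km under the common equatorial-radius convention (0.2% apart)
  expect_equal(D[1, 2], 0.01 * pi / 180 * 6371.0088, tolerance = 1e-9)
  expect_equal(D[1, 2], 1.1132, tolerance = 2e-3)
  expect_equal(D[1, 1], 0)
  # Times Square <-> JFK (Terminal 4): about 20.6 km
  lm <- data.frame(lon = c(-73.9855, -73.7822), lat = c(40.7580, 40.6446))
  expect_equal(zone_distances(lm)[1, 2], 20.6, tolerance = 0.05 * 20.6)
})
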