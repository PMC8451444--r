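# Flight-area clipping, road partition, crossing classification and
# proximity areas, checked against Monte-Carlo and sequential-split oracles.

test_that("clip_to_flight_area handles containment and disjointness", {
  area <- flight_area(c(0, 0), 10)
  unit <- field_polygon("u", cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
  got <- clip_to_flight_area(unit, area)
  expect_equal(got$s_pot, 1)
  far <- field_polygon("d", cbind(c(100, 101, 101, 100), c(0, 0, 1, 1)))
  got <- clip_to_flight_area(far, area)
  expect_equal(got$s_pot, 0)
  expect_equal(nrow(got$geometry), 0)
})

test_that("clipped areas agree with the Monte-Carlo oracle (sampled cases)", {
  set.seed(101)
  for (case in 1:6) {
    poly <- oracle_random_convex(runif(1, -50, 50), runif(1, -50, 50), 30, 80)
    r <- runif(1, 40, 90)
    f <- field_polygon("p", poly)
    got <- clip_to_flight_area(f, flight_area(c(0, 0), r))$s_pot
    mc <- mc_poly_circle_area(poly, 0, 0, r, n = 2e5, seed = 7000 + case)
    expect_lt(abs(got - mc$area), 3 * mc$se + 1e-6)
  }
})

test_that("clip_to_flight_area is monotone in radius and bounded", {
  set.seed(55)
  for (case in 1:5) {
    poly <- oracle_random_convex(runif(1, -40, 40), runif(1, -40, 40), 20, 60)
    f <- field_polygon("p", poly)
    radii <- sort(runif(5, 10, 120))
    s <- vapply(radii, function(r) clip_to_flight_area(f, flight_area(c(0, 0), r))$s_pot,
                numeric(1))
    expect_true(all(diff(s) >= -1e-9))
    expect_true(all(s <= pmin(polygon_area(poly), pi * radii^2) + 1e-6))
  }
})

test_that("partition handles the no-road and single-road cases", {
  ext <- map_extent(100, 80)
  p0 <- partition_by_roads(semantic_map(ext), c(50, 40))
  expect_length(p0$regions, 1)
  expect_equal(sum(p0$areas), 100 * 80)
  expect_equal(p0$active_region_id, 1)

  r <- road("r1", cbind(c(30, 30), c(0, 80)), "country")
  p1 <- partition_by_roads(semantic_map(ext, roads = list(r)), c(10, 40))
  expect_length(p1$regions, 2)
  expect_equal(sum(p1$areas), 100 * 80, tolerance = 1e-9)
  expect_equal(sort(p1$areas), c(30 * 80, 70 * 80), tolerance = 1e-9)
  expect_equal(p1$areas[p1$active_region_id], 30 * 80)
})

test_that("partition matches the sequential-split oracle on crossing straight roads", {
  W <- 1000; H <- 800
  lines <- list(cbind(c(200, 900), c(0, 800)),
                cbind(c(0, 1000), c(600, 100)),
                cbind(c(850, 100), c(0, 800)))
  roads <- lapply(seq_along(lines), function(i) road(paste0("r", i), lines[[i]], "country"))
  part <- partition_by_roads(semantic_map(map_extent(W, H), roads = roads), c(10, 10))
  want <- oracle_split_partition(W, H, lines)
  expect_length(part$regions, length(want))
  expect_equal(sort(part$areas), sort(want), tolerance = 1e-9)
  expect_equal(sum(part$areas), W * H, tolerance = 1e-9)
  # pairwise interior-disjointness: representative of each region is in no other
  for (i in seq_along(part$regions)) {
    rp <- apisite:::representative_point(part$regions[[i]])
    inothers <- vapply(part$regions[-i], function(g) {
      apisite:::points_in_polygon(rp[1], rp[2], g)
    }, logical(1))
    expect_false(any(inothers))
  }
})

test_that("mid-map roads are extended to the boundary before partitioning", {
  ext <- map_extent(100, 100)
  r <- road("stub", cbind(c(0, 60), c(50, 50)), "country")  # ends mid-map
  p <- partition_by_roads(semantic_map(ext, roads = list(r)), c(10, 10))
  expect_length(p$regions, 2)
  expect_equal(sum(p$areas), 1e4, tolerance = 1e-9)
})

test_that("a site on a road is flagged and assigned to the left region", {
  ext <- map_extent(100, 100)
  r <- road("r1", cbind(c(40, 40), c(0, 100)), "highway")  # direction +y, left = west
  p <- partition_by_roads(semantic_map(ext, roads = list(r)), c(40, 50))
  expect_true(p$on_road)
  expect_equal(p$areas[p$active_region_id], 40 * 100, tolerance = 1e-9)
})

test_that("crossing_class follows the road hierarchy", {
  country <- road("c", cbind(c(50, 50), c(0, 100)), "country")
  hwy <- road("h", cbind(c(70, 70), c(0, 100)), "highway")
  site <- c(10, 50)
  expect_equal(crossing_class(site, c(30, 50), list()), 1.0)
  expect_equal(crossing_class(site, c(30, 50), list(country, hwy)), 1.0)
  expect_equal(crossing_class(site, c(60, 50), list(country, hwy)), 0.7)
  expect_equal(crossing_class(site, c(90, 50), list(country, hwy)), 0.5)
  expect_equal(crossing_class(site, c(90, 50), list(hwy)), 0.5)
})

test_that("road_proximity_area handles far, contained and straddling segments", {
  r <- road("h", cbind(c(0, 0), c(-1000, 1000)), "country")  # corridor |x| <= 100
  seg_far <- cbind(c(200, 300, 300, 200), c(0, 0, 50, 50))
  expect_equal(road_proximity_area(seg_far, r), 0)
  seg_in <- cbind(c(-50, 50, 50, -50), c(0, 0, 50, 50))
  expect_equal(road_proximity_area(seg_in, r), 100 * 50, tolerance = 1e-9)
  seg_str <- cbind(c(50, 250, 250, 50), c(0, 0, 40, 40))
  expect_equal(road_proximity_area(seg_str, r), 50 * 40, tolerance = 1e-9)
})

test_that("corridor overlap areas agree with the Monte-Carlo oracle", {
  set.seed(77)
  for (case in 1:5) {
    poly <- oracle_random_convex(runif(1, -200, 200), runif(1, -200, 200), 100, 300)
    pts <- cbind(c(runif(1, -400, -200), runif(1, -100, 100), runif(1, 200, 400)),
                 runif(3, -300, 300))
    rd <- road("r", pts, sample(c("highway", "railroad", "country"), 1))
    got <- road_proximity_area(poly, rd)
    mc <- mc_poly_corridor_area(poly, pts, rd$buffer_width, n = 2e5, seed = 8800 + case)
    expect_lt(abs(got - mc$area), 3 * mc$se + 1e-6)
    expect_lte(got, polygon_area(poly) + 1e-6)
  }
})

test_that("S2 never exceeds S_pot for clipped segments", {
  set.seed(31)
  m <- tiny_map(n_fields = 12, n_roads = 3, seed = 12)
  area <- flight_area(c(5000, 5000), 3000)
  for (f in m$fields) {
    clip <- clip_to_flight_area(f, area)
    if (clip$s_pot == 0) next
    for (r in m$roads) {
      expect_lte(road_proximity_area(clip$geometry, r), clip$s_pot + 1e-6)
    }
  }
})
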