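# The yield equations and the end-to-end evaluation.

test_that("field_coefficient combines and clamps", {
  expect_equal(field_coefficient(1.0, 0.0), 1.0)
  expect_equal(field_coefficient(0.6, -1.0), 0.0)
  expect_equal(field_coefficient(0.8, -0.5), 0.3)
  expect_equal(field_coefficient(c(0.2, 1.0), c(-0.5, -1.0)), c(0, 0))
  expect_error(field_coefficient(NA, 0), "not assigned")
})

test_that("segment_yield follows the hectare unit convention and is linear", {
  p <- model_params()
  expect_equal(p$delta, 0.14)
  seg <- list(c_f = 1, c3 = 1, s_pot = 1e4)        # exactly one hectare
  expect_equal(segment_yield(seg, p), 14.0)
  seg$c_f <- 0
  expect_equal(segment_yield(seg, p), 0)
  seg2 <- list(c_f = 0.3, c3 = 0.7, s_pot = 2.5e4)
  expect_equal(segment_yield(list(c_f = 0.3, c3 = 0.7, s_pot = 5e4), p),
               2 * segment_yield(seg2, p))
})

test_that("segment_losses scale with -c4 per road and clamp at the yield", {
  p <- model_params()
  hwy <- road("h", cbind(c(0, 1), c(0, 0)), "highway")
  cty <- road("c", cbind(c(0, 1), c(0, 0)), "country")
  seg <- list(c_f = 1, c3 = 1, s_pot = 1e4, s2_by_road = c(h = 1e4))
  expect_equal(segment_losses(seg, list(hwy, cty), p), 7.0)
  seg$s2_by_road <- numeric(0)
  expect_equal(segment_losses(seg, list(hwy, cty), p), 0)
  # three full-cover highway corridors would overshoot; clamp keeps net >= 0
  roads3 <- list(hwy, road("h2", cbind(c(0, 1), c(1, 1)), "highway"),
                 road("h3", cbind(c(0, 1), c(2, 2)), "highway"))
  seg$s2_by_road <- c(h = 1e4, h2 = 1e4, h3 = 1e4)
  expect_equal(segment_losses(seg, roads3, p), segment_yield(seg, p))
  seg$s2_by_road <- c(nope = 1)
  expect_error(segment_losses(seg, roads3, p), "unknown road")
})

test_that("total_honey sums, floors at zero and is permutation-invariant", {
  expect_equal(total_honey(list()), 0)
  segs <- list(list(h_i = 14, h_losses = 7), list(h_i = 3, h_losses = 0.5))
  expect_equal(total_honey(segs), 9.5)
  expect_equal(total_honey(rev(segs)), 9.5)
})

test_that("colony_count floors and applies the survival gate", {
  p <- model_params()
  expect_identical(colony_count(7688.84, p), 51L)
  expect_identical(colony_count(89, p), 0L)      # below self-consumption
  expect_identical(colony_count(300, p), 2L)
  expect_identical(colony_count(0, p), 0L)
  expect_error(colony_count(-1, p), "non-negative")
  # gate stays active for custom parameters
  expect_identical(colony_count(50, model_params(H_colony = 10, H_average = 10)), 2L)
  expect_identical(colony_count(5, model_params(H_colony = 10, H_average = 10)), 0L)
})

test_that("evaluate_location composes the pipeline", {
  ext <- map_extent(10000, 10000)
  empty <- semantic_map(ext)
  res <- evaluate_location(empty, c(5000, 5000))
  expect_equal(res$honey, 0)
  expect_identical(res$hives, 0L)
  expect_false(res$on_road)

  # one 1-ha field at the site, fully productive, no roads -> 14 kg, 0 hives
  f <- field_polygon("f1", cbind(c(4950, 5050, 5050, 4950),
                                 c(4950, 4950, 5050, 5050)), c1 = 1.0, c2 = 0.0)
  m <- semantic_map(ext, fields = list(f))
  res <- evaluate_location(m, c(5000, 5000))
  expect_equal(res$honey, 14.0, tolerance = 1e-9)
  expect_identical(res$hives, 0L)

  # unassigned coefficients are refused
  m2 <- semantic_map(ext, fields = list(field_polygon("g", f$vertices)))
  expect_error(evaluate_location(m2, c(5000, 5000)), "unassigned")
  expect_error(evaluate_location(m, c(-5, 5000)), "outside the map extent")
})

test_that("scale converts input units; site is reported in input units", {
  # 1000 px wide file, 10 m per px
  ext <- map_extent(10000, 10000, scale = 10)
  f <- field_polygon("f1", cbind(c(4950, 5050, 5050, 4950),
                                 c(4950, 4950, 5050, 5050)), c1 = 1.0, c2 = 0.0)
  m <- semantic_map(ext, fields = list(f))
  res <- evaluate_location(m, c(500, 500))   # 500 px -> 5000 m
  expect_equal(res$honey, 14.0, tolerance = 1e-9)
  expect_equal(res$x, 500)
})

test_that("site result JSON carries exactly the five interchange keys", {
  m <- semantic_map(map_extent(100, 100))
  res <- evaluate_location(m, c(50, 50), model_params(radius = 10))
  parsed <- jsonlite::fromJSON(site_result_json(res))
  expect_named(parsed, c("x", "y", "onRoad", "honey", "hives"))
  expect_false(parsed$onRoad)
  expect_equal(parsed$honey, 0)
})

test_that("contamination monotonicity holds at the model level", {
  p <- model_params()
  for (c1 in c(0.2, 0.6, 1.0)) {
    h <- vapply(c(0, -0.5, -1), function(c2) {
      segment_yield(list(c_f = field_coefficient(c1, c2), c3 = 0.7, s_pot = 3e4), p)
    }, numeric(1))
    expect_true(all(diff(h) <= 1e-12))
  }
})
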