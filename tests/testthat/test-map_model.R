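# Domain types and the annotation-file dialect.

test_that("constructors enforce the domain invariants", {
  expect_error(map_extent(-1, 10), "positive")
  expect_error(field_polygon("f", cbind(c(0, 1), c(0, 1))), "3 vertices")
  # self-intersecting bowtie
  bow <- cbind(c(0, 1, 1, 0), c(0, 1, 0, 1))
  expect_error(field_polygon("f", bow), "self-intersecting")
  # out-of-set coefficients
  sq <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))
  expect_error(field_polygon("f", sq, c1 = 0.3), "c1")
  expect_error(field_polygon("f", sq, c1 = 0.4, c2 = 0.5), "c2")
  expect_silent(field_polygon("f", sq, c1 = 0.4, c2 = -0.5))
  expect_error(road("r", cbind(c(0, 0), c(0, 0)), "country"), "zero length")
  expect_error(road("r", cbind(c(0, 1), c(0, 1)), "footpath"))
  # derived road attributes
  r <- road("r", cbind(c(0, 100), c(0, 0)), "railroad")
  expect_equal(r$c4, -0.3)
  expect_equal(r$buffer_width, 300)
  expect_true(r$crossing_main)
  expect_false(road("r", cbind(c(0, 100), c(0, 0)), "country")$crossing_main)
})

test_that("semantic_map rejects duplicate ids and out-of-extent geometry", {
  ext <- map_extent(100, 100)
  sq <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))
  f1 <- field_polygon("a", sq)
  expect_error(semantic_map(ext, fields = list(f1, f1)), "duplicate field ids")
  far <- field_polygon("b", sq + 200)
  expect_error(semantic_map(ext, fields = list(far)), "outside the map extent")
  expect_silent(semantic_map(ext))   # empty map is valid
})

test_that("write_map / read_map round trip is lossless", {
  for (seed in c(2, 9)) {
    m <- generate_map(fixture_spec(n_fields = 15, n_roads = 4, seed = seed,
                                   scale = if (seed == 2) 1 else 13.7))
    path <- withr::local_tempfile(fileext = ".json")
    write_map(m, path)
    m2 <- read_map(path)
    expect_length(m2$fields, 15)
    expect_length(m2$roads, 4)
    expect_identical(vapply(m2$fields, `[[`, "", "id"),
                     vapply(m$fields, `[[`, "", "id"))
    # geometry to < 1e-9 m, attributes exact
    dev <- max(mapply(function(a, b) max(abs(a$vertices - b$vertices)),
                      m$fields, m2$fields))
    expect_lt(dev, 1e-9)
    expect_identical(vapply(m2$fields, `[[`, 0, "c1"), vapply(m$fields, `[[`, 0, "c1"))
    expect_identical(vapply(m2$fields, `[[`, 0, "c2"), vapply(m$fields, `[[`, 0, "c2"))
    expect_identical(vapply(m2$roads, `[[`, 0, "c4"), vapply(m$roads, `[[`, 0, "c4"))
    expect_identical(vapply(m2$roads, `[[`, "", "road_class"),
                     vapply(m$roads, `[[`, "", "road_class"))
  }
})

test_that("empty map round trips and malformed files are rejected", {
  path <- withr::local_tempfile(fileext = ".json")
  write_map(semantic_map(map_extent(500, 500)), path)
  m <- read_map(path)
  expect_length(m$fields, 0)
  expect_length(m$roads, 0)

  expect_error(read_map(file.path(tempdir(), "nope.json")), "no such file")
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"type":"FeatureCollection","properties":{"extent":{"width":100,"height":100}},
    "features":[{"type":"Feature","properties":{"kind":"field","id":"fx","c1":0.35},
    "geometry":{"type":"Polygon","coordinates":[[[0,0],[10,0],[10,10],[0,0]]]}}]}', bad)
  expect_error(read_map(bad), "fx")   # names the offending feature
})

test_that("unassigned coefficients survive the round trip as missing", {
  ext <- map_extent(100, 100)
  f <- field_polygon("f1", cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)))
  path <- withr::local_tempfile(fileext = ".json")
  write_map(semantic_map(ext, fields = list(f)), path)
  m <- read_map(path)
  expect_true(is.na(m$fields[[1]]$c1))
  expect_true(is.na(m$fields[[1]]$c2))
})
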