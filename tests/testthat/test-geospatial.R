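test_that("point_in_tract implements boundary-inclusive even-odd", {
  sq <- list(list(unit_square()))
  expect_true(point_in_tract(0.5, 0.5, sq))
  expect_false(point_in_tract(1.5, 0.5, sq))
  # boundary and corner points are inside
  expect_true(point_in_tract(0, 0.5, sq))
  expect_true(point_in_tract(1, 1, sq))
  # square with a hole: center falls in the hole -> outside
  donut <- list(list(unit_square(), unit_square(0.25, 0.25, 0.5)))
  expect_false(point_in_tract(0.5, 0.5, donut))
  expect_true(point_in_tract(0.1, 0.1, donut))
  expect_true(point_in_tract(0.25, 0.5, donut))   # hole edge counts inside
})

test_that("degenerate rings are rejected", {
  expect_error(new_tract_set("a", list(list(list(rbind(c(0, 0), c(1, 0),
                                                       c(0, 0)))))),
               "degenerate")
  expect_error(new_tract_set("a", list(list(list(rbind(c(0, 0), c(1, 0),
                                                       c(1, 1), c(0, 1)))))),
               "not closed")
  expect_error(new_tract_set(c("a", "a"),
                             list(list(list(unit_square())),
                                  list(list(unit_square(2))))),
               "duplicate")
})

test_that("multi-part tracts contain a point if any part does", {
  two_part <- list(list(unit_square(0, 0)), list(unit_square(5, 5)))
  expect_true(point_in_tract(5.5, 5.5, two_part))
  expect_true(point_in_tract(0.5, 0.5, two_part))
  expect_false(point_in_tract(2.5, 2.5, two_part))
})

test_that("assign_tracts resolves boundary ties to the smallest id", {
  grid <- square_grid(2)
  rec <- data.frame(lon = c(0.5, 1.5, 1, 3.7),
                    lat = c(0.5, 1.5, 1, 0.2))
  asn <- assign_tracts(rec, grid)
  expect_equal(asn$records$tract_id, c("01", "04", "01", NA))
  expect_equal(asn$unassigned, 1L)
  expect_equal(sum(!is.na(asn$records$tract_id)) + asn$unassigned, nrow(rec))
})

test_that("empty tract collections are a configuration error", {
  expect_error(assign_tracts(data.frame(lon = 1, lat = 1), list()),
               "empty or invalid")
})

test_that("grid-accelerated assignment equals brute force", {
  grid <- square_grid(4)
  set.seed(21)
  rec <- data.frame(lon = runif(400, -0.5, 4.5), lat = runif(400, -0.5, 4.5))
  # sprinkle exact boundary points among them
  rec$lon[1:20] <- rep(0:4, 4)[1:20]
  rec$lat[1:20] <- rep(0:4, each = 4)[1:20]
  a <- assign_tracts(rec, grid, method = "grid")
  b <- assign_tracts(rec, grid, method = "brute")
  expect_identical(a$records$tract_id, b$records$tract_id)
  expect_identical(a$unassigned, b$unassigned)
  # deterministic across repeated runs
  a2 <- assign_tracts(rec, grid, method = "grid")
  expect_identical(a$records$tract_id, a2$records$tract_id)
})

test_that("GeoJSON round-trip preserves ids and geometry", {
  grid <- square_grid(2)
  path <- tempfile(fileext = ".geojson")
  write_tracts_geojson(grid, path)
  back <- load_tracts(path)
  expect_equal(back$tract_id, grid$tract_id)
  expect_equal(back$geoms, grid$geoms)
  expect_equal(back$bbox, grid$bbox)
})

test_that("load_tracts reads MultiPolygon features and custom id fields", {
  gj <- list(type = "FeatureCollection", features = list(
    list(type = "Feature", properties = list(TID = "mp"),
         geometry = list(type = "MultiPolygon", coordinates = list(
           list(list(list(0, 0), list(1, 0), list(1, 1), list(0, 1),
                     list(0, 0))),
           list(list(list(5, 5), list(6, 5), list(6, 6), list(5, 6),
                     list(5, 5)))
         )))
  ))
  path <- tempfile(fileext = ".geojson")
  writeLines(jsonlite::toJSON(gj, auto_unbox = TRUE), path)
  ts <- load_tracts(path, id_property = "TID")
  expect_equal(ts$tract_id, "mp")
  expect_length(ts$geoms[[1]], 2L)
  expect_error(load_tracts(path), "missing id property")
})
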