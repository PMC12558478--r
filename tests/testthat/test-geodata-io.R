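write_poly_geojson <- function(path, polys_coords, damage, ids = NULL) {
  feats <- lapply(seq_along(polys_coords), function(k) {
    list(type = "Feature",
         properties = list(building_id = ids[k] %||% sprintf("b%d", k),
                           damage = damage[k]),
         geometry = list(type = "Polygon", coordinates = polys_coords[k]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  path
}
`%||%` <- function(a, b) if (is.null(a)) b else a

square_coords <- function(cx, cy, s) {
  lapply(list(c(-1, -1), c(1, -1), c(1, 1), c(-1, 1), c(-1, -1)),
         function(u) c(cx + u[1] * s / 2, cy + u[2] * s / 2))
}

test_that("polygon reader normalizes percent damage and preserves counts", {
  f <- withr::local_tempfile(fileext = ".geojson")
  write_poly_geojson(f, list(square_coords(0, 0, 10), square_coords(20, 0, 10),
                             square_coords(40, 0, 10)),
                     damage = c(0, 40, 95))
  expect_message(polys <- read_damage_polygons(f), "percentages")
  expect_equal(nrow(polys), 3)
  expect_equal(polys$damage_fraction, c(0, 0.40, 0.95))
  expect_equal(nrow(attr(polys, "rejected")), 0)

  # already-fractional values are left alone
  f2 <- withr::local_tempfile(fileext = ".geojson")
  write_poly_geojson(f2, list(square_coords(0, 0, 10)), damage = 0.6)
  expect_equal(read_damage_polygons(f2)$damage_fraction, 0.6)
})

test_that("empty collections, bad fields and bad geometry types error or warn", {
  f <- withr::local_tempfile(fileext = ".geojson")
  jsonlite::write_json(list(type = "FeatureCollection", features = list()),
                       f, auto_unbox = TRUE)
  expect_warning(out <- read_damage_polygons(f), "empty")
  expect_equal(nrow(out), 0)

  f2 <- withr::local_tempfile(fileext = ".geojson")
  write_poly_geojson(f2, list(square_coords(0, 0, 10)), damage = NA)
  expect_error(read_damage_polygons(f2), "damage field")

  expect_error(read_damage_polygons("does-not-exist.geojson"), "not found")
  expect_error(read_damage_polygons("x.gpkg"), "GeoPackage")
})

test_that("self-intersecting footprints are repaired against the clipping oracle", {
  f <- withr::local_tempfile(fileext = ".geojson")
  bow <- list(c(0, 0), c(10, 10), c(10, 0), c(0, 10), c(0, 0))
  write_poly_geojson(f, list(bow), damage = 0.8)
  polys <- read_damage_polygons(f)
  expect_equal(nrow(polys), 2)  # two lobes, parent damage kept
  expect_equal(polys$damage_fraction, c(0.8, 0.8))
  total <- sum(vapply(polys$geometry, poly_area, 0))
  expect_equal(total, 50, tolerance = 1e-9)
  skip_if_not(shapely_available(), "python/shapely oracle unavailable")
  m <- matrix(c(0, 0, 10, 10, 10, 0, 0, 10), ncol = 2, byrow = TRUE)
  expect_equal(total, shapely_valid_area(m), tolerance = 1e-9)
})

test_that("multipolygons split into parts that keep the parent damage", {
  f <- withr::local_tempfile(fileext = ".geojson")
  feats <- list(list(
    type = "Feature",
    properties = list(building_id = "m1", damage = 0.7),
    geometry = list(type = "MultiPolygon",
                    coordinates = list(list(square_coords(0, 0, 10)),
                                       list(square_coords(30, 0, 6))))))
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       f, auto_unbox = TRUE, digits = NA)
  polys <- read_damage_polygons(f)
  expect_equal(polys$building_id, c("m1_p1", "m1_p2"))
  expect_equal(polys$damage_fraction, c(0.7, 0.7))
})

test_that("centroid reader validates classes, resolves scores, rejects dup ids", {
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(building_id = paste0("c", 1:5),
                              x = 1:5, y = 1:5,
                              damage_class = c(1, 0, 0, 1, 1)),
                   f, row.names = FALSE)
  cents <- read_damage_centroids(f)
  expect_equal(sum(cents$damage_class), 3)

  f2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(building_id = c("a", "b"), x = 1:2, y = 1:2,
                              score = c(0.2, 0.9)), f2, row.names = FALSE)
  out <- read_damage_centroids(f2, score_field = "score",
                               score_threshold = 0.5)
  expect_equal(out$damage_class, c(0L, 1L))
  expect_error(read_damage_centroids(f2, score_field = "score"),
               "score_threshold")

  f3 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(building_id = c("dup", "dup"), x = 1:2,
                              y = 1:2, damage_class = c(0, 1)),
                   f3, row.names = FALSE)
  expect_error(read_damage_centroids(f3), "dup")

  f4 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(building_id = "a", x = 1, y = 1,
                              damage_class = 2), f4, row.names = FALSE)
  expect_error(read_damage_centroids(f4), "\\{0, 1\\}")
})

test_that("facility reader validates ranges and types, preserves order", {
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(
    facility_id = c("h1", "p1"), name = c("Hospital X", "Pharmacy Y"),
    ftype = c("hospital", "pharmacy"), city = "Antakya",
    lon = c(36.16, 36.17), lat = c(36.20, 36.21)), f, row.names = FALSE)
  fac <- read_facilities(f)
  expect_equal(fac$facility_id, c("h1", "p1"))
  expect_true(all(c("x", "y") %in% names(fac)))

  f2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(facility_id = "h1", name = "H",
                              ftype = "hospital", city = "A",
                              lon = 36, lat = 123), f2, row.names = FALSE)
  expect_error(read_facilities(f2), "range")

  f3 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(facility_id = "c1", name = "C",
                              ftype = "clinic", city = "A",
                              lon = 36, lat = 36), f3, row.names = FALSE)
  expect_error(read_facilities(f3), "unknown facility type")
})

test_that("write/read round-trips reproduce records field-for-field", {
  city <- generate_city(n_buildings = 60, counts = c(hospital = 1,
                        dialysis = 1, pharmacy = 5), err = no_errors(),
                        seed = 5)
  dir <- withr::local_tempdir()
  write_city(city, dir)
  anchor <- c(36.16, 36.20)
  prj <- local_projection(anchor[1], anchor[2])

  polys <- read_damage_polygons(file.path(dir, "model_a.geojson"),
                                proj = prj)
  expect_equal(polys$building_id, city$model_a$building_id)
  expect_equal(polys$damage_fraction, city$model_a$damage_fraction,
               tolerance = 1e-9)
  a0 <- vapply(city$model_a$geometry, poly_area, 0)
  a1 <- vapply(polys$geometry, poly_area, 0)
  expect_equal(a1, a0, tolerance = 1e-6)

  cents <- read_damage_centroids(file.path(dir, "model_b.geojson"),
                                 proj = prj)
  expect_equal(cents$building_id, city$model_b$building_id)
  expect_equal(cents$damage_class, city$model_b$damage_class)
  expect_equal(cents$x, city$model_b$x, tolerance = 1e-6)

  fac <- read_facilities(file.path(dir, "facilities.csv"), proj = prj)
  expect_equal(fac$facility_id, city$facilities$facility_id)
  expect_equal(fac$x, city$facilities$x, tolerance = 1e-6)
  expect_equal(fac$gold_label, city$facilities$gold_label)
})

test_that("deduplication matches the pairwise union-find oracle and is idempotent", {
  # one transitive triplet (pairwise < radius) + singletons
  fac <- make_fac(x = c(0, 3, 6, 500, 900, 1300),
                  y = rep(0, 6))
  fac$name <- c("Hospital X", "hospital x", "HOSPITAL  X.",
                "Hospital X", "Clinic A", "Clinic B")
  dd <- deduplicate_facilities(fac, radius_m = 10)
  expect_equal(nrow(dd$kept), 4)
  expect_setequal(dd$kept$facility_id, brute_dedup(fac, 10))
  expect_equal(nrow(dd$removed), 2)

  # same name far apart is kept (distance guard)
  far <- make_fac(x = c(0, 500), y = c(0, 0))
  far$name <- c("Hospital X", "Hospital X")
  expect_equal(nrow(deduplicate_facilities(far, 10)$kept), 2)

  # idempotent
  dd2 <- deduplicate_facilities(dd$kept, radius_m = 10)
  expect_equal(dd2$kept, dd$kept)

  # randomized instances against the oracle
  for (s in 1:5) {
    set.seed(s)
    n <- 25
    rf <- make_fac(x = runif(n, 0, 60), y = runif(n, 0, 60))
    rf$name <- sample(c("A", "B", "C"), n, replace = TRUE)
    expect_setequal(deduplicate_facilities(rf, 15)$kept$facility_id,
                    brute_dedup(rf, 15))
  }
})

test_that("S1-style facility tables read through a column mapping", {
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(
    id = c("h1", "p1"), nm = c("H", "P"), kind = c("hospital", "pharmacy"),
    region = "A", lon = c(36.1, 36.2), lat = c(36.1, 36.2),
    pct_a = c(0.55, 0.1), cls_b = c(1, 0), truth = c(1, NA)),
    f, row.names = FALSE)
  tab <- read_facility_table(f, col_map = c(
    facility_id = "id", name = "nm", ftype = "kind", city = "region",
    model_a_fraction = "pct_a", model_b_class = "cls_b",
    gold_label = "truth"))
  expect_equal(tab$model_a_fraction, c(0.55, 0.1))
  expect_equal(tab$model_b_class, c(1, 0))
  expect_error(read_facility_table(f, col_map = c(model_b_class = "nope")),
               "not in file")
})
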