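test_that("building generation is deterministic and non-overlapping", {
  b1 <- generate_buildings(60, seed = 1)
  b2 <- generate_buildings(60, seed = 1)
  expect_identical(b1, b2)
  b3 <- generate_buildings(60, seed = 2)
  expect_false(identical(b1$cx, b3$cx))

  # brute-force O(n^2) overlap oracle
  for (s in 1:3) {
    b <- generate_buildings(50, seed = s)
    for (i in 1:(nrow(b) - 1)) for (j in (i + 1):nrow(b)) {
      expect_false(rects_overlap(
        c(b$cx[i], b$cy[i], b$w[i], b$h[i]),
        c(b$cx[j], b$cy[j], b$w[j], b$h[j])),
        label = sprintf("seed %d: buildings %d/%d overlap", s, i, j))
    }
  }
})

test_that("zone structure: dense gaps below merge distance, sparse spacing respected", {
  b <- generate_buildings(80, dense_fraction = 0.5, seed = 4)
  dense <- b[b$zone == "dense", ]
  for (cl in unique(dense$cluster_id)) {
    blk <- dense[dense$cluster_id == cl, ]
    if (nrow(blk) < 2) next
    # every dense building has a block neighbour within the merge distance
    for (i in seq_len(nrow(blk))) {
      gaps <- vapply(seq_len(nrow(blk))[-i], function(j) {
        rect_gap(c(blk$cx[i], blk$cy[i], blk$w[i], blk$h[i]),
                 c(blk$cx[j], blk$cy[j], blk$w[j], blk$h[j]))
      }, 0)
      expect_lt(min(gaps), 6)
    }
  }

  sp <- generate_buildings(100, dense_fraction = 0, seed = 5)
  expect_true(all(sp$zone == "sparse"))
  d <- as.matrix(stats::dist(cbind(sp$cx, sp$cy)))
  diag(d) <- Inf
  expect_gte(min(d), 52)

  expect_error(generate_buildings(200, bounds = c(0, 0, 200, 200), seed = 1),
               "too small")
})

test_that("true damage follows the clamped exponential decay", {
  b <- generate_buildings(40, dense_fraction = 0, seed = 7,
                          bounds = c(0, 0, 3000, 3000))
  d0 <- 500
  # noise-free: exact closed form at each building
  bd <- assign_true_damage(b, epicenter = c(b$cx[1], b$cy[1]), d0 = d0,
                           noise_sd = 0, seed = 1)
  expect_equal(bd$true_damage_fraction[1], 1.0)  # at the epicenter
  d <- sqrt((bd$cx - bd$cx[1])^2 + (bd$cy - bd$cy[1])^2)
  expect_equal(bd$true_damage_fraction, pmin(pmax(exp(-d / d0), 0), 1))

  # a building exactly at d0 * ln 2 has fraction 0.5
  one <- tibble::tibble(building_id = "b1", zone = "sparse",
                        size_class = "small", cluster_id = NA_integer_,
                        cx = d0 * log(2), cy = 0, w = 10, h = 10,
                        cluster_cx = NA_real_, cluster_cy = NA_real_)
  expect_equal(assign_true_damage(one, epicenter = c(0, 0), d0 = d0,
                                  noise_sd = 0, seed = 1)$true_damage_fraction,
               0.5)

  # Monte-Carlo: noisy mean within 3 SE of the noise-free mean
  big <- generate_buildings(1000, dense_fraction = 0, seed = 8,
                            bounds = c(0, 0, 8000, 8000), sparse_min_dist = 30)
  noise_free <- assign_true_damage(big, d0 = 800, noise_sd = 0, seed = 1,
                                   epicenter = c(4000, 4000))
  noisy <- assign_true_damage(big, d0 = 800, noise_sd = 0.1, seed = 2,
                              epicenter = c(4000, 4000))
  # clamping biases the noisy mean upward near 0; compare on mid-range bldgs
  mid <- noise_free$true_damage_fraction > 0.3 &
    noise_free$true_damage_fraction < 0.7
  se <- 0.1 / sqrt(sum(mid))
  expect_lt(abs(mean(noisy$true_damage_fraction[mid]) -
                mean(noise_free$true_damage_fraction[mid])), 3 * se)
})

test_that("error-free model outputs reproduce truth exactly", {
  city <- generate_city(n_buildings = 120, counts = c(hospital = 2,
                        dialysis = 1, pharmacy = 10), err = no_errors(),
                        noise_sd = 0, seed = 9)
  expect_equal(nrow(city$model_a), nrow(city$buildings))
  expect_equal(city$model_a$damage_fraction,
               city$buildings$true_damage_fraction)
  expect_equal(nrow(city$model_b), nrow(city$buildings))
  expect_equal(city$model_b$damage_class,
               as.integer(city$buildings$true_damage_fraction > 0.40))
})

test_that("merged pairs use the area-weighted mean fraction", {
  b <- tibble::tibble(
    building_id = c("b1", "b2"), zone = "dense", size_class = "small",
    cluster_id = 1L, cx = c(0, 12), cy = 0, w = c(10, 17.32), h = c(10, 17.32),
    cluster_cx = 6, cluster_cy = 0,
    true_damage_fraction = c(1, 0), destroyed = c(TRUE, FALSE))
  # areas 100 and ~300; fractions 1 and 0 -> merged ~0.25
  ma <- simulate_model_a(b, error_params(p_merge = 1, p_destroyed_miss = 0,
                                         p_multi_centroid = 0,
                                         geocode_sigma_m = 0,
                                         p_geocode_outside = 0),
                         seed = 1, merge_dist = 20)
  expect_equal(nrow(ma), 1)
  expect_equal(ma$building_id, "b1+b2")
  a1 <- 100; a2 <- 17.32^2
  expect_equal(ma$damage_fraction, a1 / (a1 + a2), tolerance = 1e-6)
  # merged polygon covers both footprints
  expect_true(point_in_poly(0, 0, ma$geometry[[1]]))
  expect_true(point_in_poly(12, 0, ma$geometry[[1]]))
})

test_that("destroyed-miss caps emitted fractions at 0.2 for every destroyed building", {
  city <- generate_city(n_buildings = 200, counts = c(pharmacy = 5),
                        d0 = 2000,  # slow decay: a sizeable destroyed core
                        err = error_params(p_merge = 0, p_multi_centroid = 0,
                                           p_destroyed_miss = 1,
                                           geocode_sigma_m = 0,
                                           p_geocode_outside = 0),
                        seed = 10)
  destroyed_ids <- city$buildings$building_id[city$buildings$destroyed]
  expect_gt(length(destroyed_ids), 0)
  emitted <- city$model_a[city$model_a$building_id %in% destroyed_ids, ]
  expect_equal(nrow(emitted), length(destroyed_ids))
  expect_true(all(emitted$damage_fraction <= 0.2))
  expect_true(all(!classify_polygon(emitted$damage_fraction, 0.40)))
  # and the centroid dialect emits class 0 for all of them
  cb <- city$model_b[city$model_b$building_id %in% destroyed_ids, ]
  expect_true(all(cb$damage_class == 0))
})

test_that("multi-centroid splitting emits per-wing classes", {
  b <- tibble::tibble(
    building_id = "big", zone = "sparse", size_class = "large",
    cluster_id = NA_integer_, cx = 0, cy = 0, w = 30, h = 20,
    cluster_cx = NA_real_, cluster_cy = NA_real_,
    true_damage_fraction = 1 / 3, destroyed = FALSE)
  err1 <- error_params(p_merge = 0, p_multi_centroid = 1,
                       p_destroyed_miss = 0, geocode_sigma_m = 0,
                       p_geocode_outside = 0)
  # find a seed drawing k = 3 wings
  for (s in 1:20) {
    mb <- simulate_model_b(b, err1, seed = s)
    if (nrow(mb) == 3) break
  }
  expect_equal(nrow(mb), 3)
  # one damaged wing of three: exactly one class-1 centroid
  expect_equal(sum(mb$damage_class), 1)
  # wing centroids stay inside the footprint
  expect_true(all(point_in_poly(mb$x, mb$y, rect_ring(0, 0, 30, 20))))

  # centroid count expectation: n + Binomial(large, p) * (k - 1), k ~ U{2,3}
  ns <- vapply(1:200, function(s) {
    city <- generate_buildings(60, seed = s, dense_fraction = 0.3)
    city <- assign_true_damage(city, seed = s)
    nrow(simulate_model_b(city, err1, seed = s)) - nrow(city)
  }, 0)
  n_large <- mean(vapply(1:20, function(s) {
    sum(generate_buildings(60, seed = s, dense_fraction = 0.3)$size_class ==
        "large")
  }, 0))
  expected_extra <- n_large * 1 * 1.5  # p = 1, mean(k - 1) = 1.5
  se <- stats::sd(ns) / sqrt(length(ns))
  expect_lt(abs(mean(ns) - expected_extra), 3 * se + 1)
})

test_that("facility placement respects hosts, jitter and outside displacement", {
  city <- generate_buildings(150, seed = 11)
  city <- assign_true_damage(city, seed = 11)

  fac <- place_facilities(city, counts = c(hospital = 2, dialysis = 1,
                                           pharmacy = 10),
                          err = no_errors(), seed = 11)
  expect_equal(as.integer(table(fac$ftype)[c("hospital", "dialysis",
                                             "pharmacy")]),
               c(2L, 1L, 10L))
  # zero jitter: every point inside its host footprint
  for (i in seq_len(nrow(fac))) {
    host <- city[city$building_id == fac$host_building_id[i], ]
    expect_true(point_in_poly(fac$x[i], fac$y[i], building_ring(host)))
    if (fac$ftype[i] == "hospital") expect_equal(host$size_class, "large")
  }
  # gold labels match the thresholded truth of the host
  hosts <- match(fac$host_building_id, city$building_id)
  expect_equal(fac$gold_label,
               as.integer(city$true_damage_fraction[hosts] > 0.40))

  # forced outside displacement: outside but within 5 m of the boundary
  out <- place_facilities(city, counts = c(pharmacy = 20),
                          err = error_params(p_geocode_outside = 1,
                                             geocode_sigma_m = 0,
                                             p_merge = 0,
                                             p_multi_centroid = 0,
                                             p_destroyed_miss = 0),
                          seed = 12)
  for (i in seq_len(nrow(out))) {
    host <- city[city$building_id == out$host_building_id[i], ]
    ring <- building_ring(host)
    expect_false(point_in_poly(out$x[i], out$y[i], ring))
    gap <- rect_gap(c(host$cx, host$cy, host$w, host$h),
                    c(out$x[i], out$y[i], 0, 0))
    expect_gte(gap, 1 - 1e-9); expect_lte(gap, 5 + 1e-9)
  }

  expect_error(place_facilities(city, counts = c(hospital = 500),
                                err = no_errors(), seed = 1),
               "not enough host buildings")
})

test_that("a city regenerates bit-for-bit from its provenance", {
  city <- generate_city(n_buildings = 80, counts = c(hospital = 1,
                        pharmacy = 6), err = error_params(), seed = 13)
  p <- city$provenance
  city2 <- generate_city(
    n_buildings = p$n_buildings, bounds = p$bounds,
    dense_fraction = p$dense_fraction, epicenter = p$epicenter, d0 = p$d0,
    noise_sd = p$noise_sd, destruction_cut = p$destruction_cut,
    counts = unlist(p$counts), err = do.call(error_params, p$err),
    th = do.call(thresholds, p$thresholds), seed = p$seed,
    city_name = p$city_name)
  expect_identical(city$buildings, city2$buildings)
  expect_identical(city$facilities, city2$facilities)
  expect_identical(city$model_a, city2$model_a)
  expect_identical(city$model_b, city2$model_b)

  # serialized city is byte-identical across writes
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_city(city, d1); write_city(city2, d2)
  for (fn in list.files(d1)) {
    expect_identical(readLines(file.path(d1, fn)),
                     readLines(file.path(d2, fn)), label = fn)
  }
})
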