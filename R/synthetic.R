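# Synthetic post-earthquake city generator.
#
# Produces a ground-truth building stock (clustered rectangular footprints),
# a spatially decaying true-damage field, typed health facilities with gold
# labels, and the two model-output dialects with injectable error modes:
# dense-zone polygon merging, multi-centroid assignment on large buildings,
# destroyed-building misses, and facility geocoding offsets. Everything is
# deterministic given the seed.

capitalize <- function(s) paste0(toupper(substring(s, 1L, 1L)), substring(s, 2L))

# derive a reproducible sub-seed for a named stage
sub_seed <- function(seed, stage) {
  (as.integer(seed) * 31L + sum(utf8ToInt(stage))) %% 2147483587L
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}

#' Generate a synthetic building stock
#'
#' Places `n` non-overlapping axis-aligned rectangular footprints inside
#' `bounds`. A fraction of the stock sits in dense blocks: tight clusters of
#' small buildings whose nearest-neighbour gaps stay below the polygon
#' merge distance used by [simulate_model_a()]. The remainder is sparse,
#' with building centroids kept at least `sparse_min_dist` apart (so no
#' sparse neighbour falls inside the 25 m rescue radius of another), and a
#' share of large footprints able to host hospitals.
#'
#' @param n Number of buildings (>= 1).
#' @param bounds City rectangle `c(xmin, ymin, xmax, ymax)` in meters.
#' @param dense_fraction Fraction of buildings placed in dense blocks.
#' @param seed Integer seed; the layout is a pure function of the arguments.
#' @param cluster_size Target buildings per dense block.
#' @param small_side,large_side Ranges (m) for small/large footprint sides.
#' @param gap_dense Range (m) of gaps between neighbours within a block;
#'   keep the upper end below the merge distance.
#' @param sparse_min_dist Minimum centroid separation (m) between sparse
#'   buildings; keep above `sqrt(2) * max(large_side)` so footprints cannot
#'   overlap and above the rescue radius so sparse neighbours never bleed
#'   into each other's 25 m disc. Default 52.
#' @param large_prob_sparse Probability a sparse building is large.
#' @param max_tries Rejection-sampling budget per placement before erroring.
#' @return Tibble with `building_id`, `zone`, `size_class`, `cluster_id`,
#'   `cx`, `cy`, `w`, `h`, `cluster_cx`, `cluster_cy`.
#' @export
generate_buildings <- function(n, bounds = c(0, 0, 2000, 2000),
                               dense_fraction = 0.5, seed = 1L,
                               cluster_size = 9L,
                               small_side = c(8, 14), large_side = c(22, 36),
                               gap_dense = c(2.5, 4.5),
                               sparse_min_dist = 52,
                               large_prob_sparse = 0.3,
                               max_tries = 500L) {
  stopifnot(n >= 1, dense_fraction >= 0, dense_fraction <= 1,
            bounds[3L] > bounds[1L], bounds[4L] > bounds[2L])
  with_seed(sub_seed(seed, "buildings"), {
    n_dense <- round(n * dense_fraction)
    n_sparse <- n - n_dense
    margin <- 60
    rows <- list()

    # dense blocks: jittered grids of small rectangles
    cluster_centers <- matrix(numeric(0), ncol = 2)
    if (n_dense > 0L) {
      n_clusters <- ceiling(n_dense / cluster_size)
      sizes <- rep(cluster_size, n_clusters)
      sizes[n_clusters] <- n_dense - cluster_size * (n_clusters - 1L)
      block_extent <- ceiling(sqrt(cluster_size)) *
        (small_side[2L] + gap_dense[2L])
      for (cl in seq_len(n_clusters)) {
        ok <- FALSE
        for (try in seq_len(max_tries)) {
          cc <- c(stats::runif(1, bounds[1L] + margin, bounds[3L] - margin),
                  stats::runif(1, bounds[2L] + margin, bounds[4L] - margin))
          if (nrow(cluster_centers) == 0L ||
              min(sqrt(rowSums((cluster_centers -
                                matrix(cc, nrow(cluster_centers), 2,
                                       byrow = TRUE))^2))) >
              2.2 * block_extent) {
            ok <- TRUE; break
          }
        }
        if (!ok) stop("bounds too small to place dense blocks", call. = FALSE)
        cluster_centers <- rbind(cluster_centers, cc)
        m <- sizes[cl]
        ncols <- ceiling(sqrt(m))
        # one square footprint size per block: row-house blocks keep every
        # neighbour gap inside [gap - 1, gap + 1], below the merge distance
        s <- stats::runif(1, small_side[1L], small_side[2L])
        pitch <- s + stats::runif(1, gap_dense[1L], gap_dense[2L])
        for (b in seq_len(m)) {
          gi <- (b - 1L) %% ncols
          gj <- (b - 1L) %/% ncols
          rows[[length(rows) + 1L]] <- list(
            zone = "dense", size_class = "small", cluster_id = cl,
            cx = cc[1L] + (gi - (ncols - 1) / 2) * pitch +
              stats::runif(1, -0.5, 0.5),
            cy = cc[2L] + (gj - (ncols - 1) / 2) * pitch +
              stats::runif(1, -0.5, 0.5),
            w = s, h = s, cluster_cx = cc[1L], cluster_cy = cc[2L])
        }
      }
    }

    # sparse buildings: rejection-sampled with centroid-distance guards
    sp_xy <- matrix(numeric(0), ncol = 2)
    block_guard <- if (n_dense > 0L) {
      ceiling(sqrt(cluster_size)) * (small_side[2L] + gap_dense[2L]) / 2 + 55
    } else 0
    for (b in seq_len(n_sparse)) {
      large <- stats::runif(1) < large_prob_sparse
      side <- if (large) large_side else small_side
      w <- stats::runif(1, side[1L], side[2L])
      h <- stats::runif(1, side[1L], side[2L])
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        p <- c(stats::runif(1, bounds[1L] + 25, bounds[3L] - 25),
               stats::runif(1, bounds[2L] + 25, bounds[4L] - 25))
        far_sparse <- nrow(sp_xy) == 0L ||
          min(sqrt(rowSums((sp_xy - matrix(p, nrow(sp_xy), 2,
                                           byrow = TRUE))^2))) >=
          sparse_min_dist
        far_blocks <- nrow(cluster_centers) == 0L ||
          min(sqrt(rowSums((cluster_centers -
                            matrix(p, nrow(cluster_centers), 2,
                                   byrow = TRUE))^2))) >= block_guard
        if (far_sparse && far_blocks) { ok <- TRUE; break }
      }
      if (!ok) stop("bounds too small to place sparse buildings",
                    call. = FALSE)
      sp_xy <- rbind(sp_xy, p)
      rows[[length(rows) + 1L]] <- list(
        zone = "sparse", size_class = if (large) "large" else "small",
        cluster_id = NA_integer_, cx = p[1L], cy = p[2L], w = w, h = h,
        cluster_cx = NA_real_, cluster_cy = NA_real_)
    }

    out <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
    out$building_id <- sprintf("b%04d", seq_len(nrow(out)))
    out[c("building_id", "zone", "size_class", "cluster_id",
          "cx", "cy", "w", "h", "cluster_cx", "cluster_cy")]
  })
}

#' Footprint ring of a synthetic building row
#'
#' @param b One-row slice of a building tibble.
#' @return Closed 5 x 2 ring matrix.
#' @export
building_ring <- function(b) rect_ring(b$cx, b$cy, b$w, b$h)

#' Assign the true damage field
#'
#' True damaged fraction decays exponentially with distance from the
#' epicenter, `clamp(exp(-d / d0) + N(0, noise_sd), 0, 1)`. Sparse
#' buildings use their own centroid distance; dense-zone buildings use
#' their block centre, so damage is coherent at the block scale (city
#' blocks collapse together, which also makes error-free recovery exact —
#' see the methods vignette). Buildings at or above `destruction_cut` are
#' flagged `destroyed`.
#'
#' @param buildings Tibble from [generate_buildings()].
#' @param epicenter `c(x, y)` in meters.
#' @param d0 Decay scale in meters (> 0).
#' @param noise_sd SD of additive Gaussian noise on the fraction.
#' @param destruction_cut Fraction at/above which a building counts as
#'   destroyed (rubble). Default 0.8.
#' @param seed Integer seed.
#' @return `buildings` with `true_damage_fraction` and `destroyed` added.
#' @export
assign_true_damage <- function(buildings, epicenter = c(1000, 1000),
                               d0 = 500, noise_sd = 0.1,
                               destruction_cut = 0.8, seed = 1L) {
  stopifnot(d0 > 0, destruction_cut > 0, destruction_cut <= 1, noise_sd >= 0)
  with_seed(sub_seed(seed, "damage"), {
    ex <- ifelse(buildings$zone == "dense", buildings$cluster_cx, buildings$cx)
    ey <- ifelse(buildings$zone == "dense", buildings$cluster_cy, buildings$cy)
    d <- sqrt((ex - epicenter[1L])^2 + (ey - epicenter[2L])^2)
    f <- exp(-d / d0) + stats::rnorm(nrow(buildings), 0, noise_sd)
    buildings$true_damage_fraction <- pmin(pmax(f, 0), 1)
    buildings$destroyed <- buildings$true_damage_fraction >= destruction_cut
    buildings
  })
}

#' Simulate the polygon model dialect
#'
#' Emits one damage polygon per building with `damage_fraction` equal to
#' the true fraction, degraded by two error modes: (i) with probability
#' `p_destroyed_miss`, a destroyed building's fraction is replaced by a
#' uniform draw on \[0, 0.2\] (the model sees rubble, not a building);
#' (ii) with probability `p_merge`, a dense-zone building is merged with
#' its nearest unmerged block neighbour within `merge_dist` into a single
#' polygon (the bounding box of the pair) whose fraction is the
#' area-weighted mean — diluting concentrated damage.
#'
#' @param city A list with `buildings` (damage assigned), or the building
#'   tibble itself.
#' @param err [error_params()].
#' @param seed Integer seed.
#' @param merge_dist Max footprint gap (m) for a mergeable pair. Default 6.
#' @return Tibble of damage polygons (`building_id`, `geometry`,
#'   `damage_fraction`).
#' @export
simulate_model_a <- function(city, err = error_params(), seed = 1L,
                             merge_dist = 6) {
  b <- if (is.data.frame(city)) city else city$buildings
  stopifnot("true_damage_fraction" %in% names(b))
  with_seed(sub_seed(seed, "model_a"), {
    frac <- b$true_damage_fraction
    miss <- b$destroyed & stats::runif(nrow(b)) < err$p_destroyed_miss
    frac[miss] <- stats::runif(sum(miss), 0, 0.2)

    merged_with <- rep(NA_integer_, nrow(b))
    if (err$p_merge > 0) {
      dense_idx <- which(b$zone == "dense")
      merge_draw <- stats::runif(nrow(b)) < err$p_merge
      for (i in dense_idx) {
        if (!is.na(merged_with[i]) || !merge_draw[i]) next
        mates <- dense_idx[b$cluster_id[dense_idx] == b$cluster_id[i] &
                           dense_idx != i & is.na(merged_with[dense_idx])]
        if (!length(mates)) next
        gaps <- vapply(mates, function(j) {
          rect_gap(c(b$cx[i], b$cy[i], b$w[i], b$h[i]),
                   c(b$cx[j], b$cy[j], b$w[j], b$h[j]))
        }, 0)
        mates <- mates[gaps < merge_dist]
        gaps <- gaps[gaps < merge_dist]
        if (!length(mates)) next
        j <- mates[which.min(gaps)]
        merged_with[i] <- j; merged_with[j] <- i
      }
    }

    ids <- character(); geoms <- list(); out_frac <- numeric()
    done <- rep(FALSE, nrow(b))
    for (i in seq_len(nrow(b))) {
      if (done[i]) next
      j <- merged_with[i]
      if (!is.na(j) && !done[j]) {
        a1 <- b$w[i] * b$h[i]; a2 <- b$w[j] * b$h[j]
        x1 <- min(b$cx[i] - b$w[i] / 2, b$cx[j] - b$w[j] / 2)
        x2 <- max(b$cx[i] + b$w[i] / 2, b$cx[j] + b$w[j] / 2)
        y1 <- min(b$cy[i] - b$h[i] / 2, b$cy[j] - b$h[j] / 2)
        y2 <- max(b$cy[i] + b$h[i] / 2, b$cy[j] + b$h[j] / 2)
        ids <- c(ids, paste(b$building_id[i], b$building_id[j], sep = "+"))
        geoms <- c(geoms, list(list(rect_ring((x1 + x2) / 2, (y1 + y2) / 2,
                                              x2 - x1, y2 - y1))))
        out_frac <- c(out_frac, (a1 * frac[i] + a2 * frac[j]) / (a1 + a2))
        done[i] <- TRUE; done[j] <- TRUE
      } else {
        ids <- c(ids, b$building_id[i])
        geoms <- c(geoms, list(list(building_ring(b[i, ]))))
        out_frac <- c(out_frac, frac[i])
        done[i] <- TRUE
      }
    }
    tibble::tibble(building_id = ids, geometry = geoms,
                   damage_fraction = out_frac)
  })
}

#' Simulate the centroid model dialect
#'
#' Emits one centroid per building with `damage_class = (true fraction >
#' cut)`, degraded by: (i) destroyed-miss (class forced to 0 with
#' probability `p_destroyed_miss`); (ii) multi-centroid assignment — with
#' probability `p_multi_centroid` a large building is emitted as k (uniform
#' on \{2, 3\}) centroids, one per equal-width vertical wing, each
#' classified from its wing's damage sub-fraction. Wing sub-fractions
#' concentrate the building's damage from the first wing onward (wing j
#' gets `clamp(k*f - (j-1), 0, 1)`, preserving the building mean), so a
#' building with one damaged wing in three yields exactly one damaged
#' centroid.
#'
#' @inheritParams simulate_model_a
#' @param cut Damaged-fraction cut used to binarize truth; default the
#'   standard 0.40.
#' @return Tibble of damage centroids (`building_id`, `x`, `y`,
#'   `damage_class`).
#' @export
simulate_model_b <- function(city, err = error_params(), seed = 1L,
                             cut = 0.40) {
  b <- if (is.data.frame(city)) city else city$buildings
  stopifnot("true_damage_fraction" %in% names(b))
  with_seed(sub_seed(seed, "model_b"), {
    miss <- b$destroyed & stats::runif(nrow(b)) < err$p_destroyed_miss
    multi <- b$size_class == "large" & !miss &
      stats::runif(nrow(b)) < err$p_multi_centroid
    k_draw <- sample(2:3, nrow(b), replace = TRUE)

    ids <- character(); xs <- numeric(); ys <- numeric(); cls <- integer()
    for (i in seq_len(nrow(b))) {
      f <- if (miss[i]) 0 else b$true_damage_fraction[i]
      if (multi[i]) {
        k <- k_draw[i]
        wing_f <- pmin(pmax(k * f - (seq_len(k) - 1L), 0), 1)
        wing_w <- b$w[i] / k
        wing_x <- b$cx[i] - b$w[i] / 2 + wing_w * (seq_len(k) - 0.5)
        ids <- c(ids, paste0(b$building_id[i], "_c", seq_len(k)))
        xs <- c(xs, wing_x); ys <- c(ys, rep(b$cy[i], k))
        cls <- c(cls, as.integer(wing_f > cut))
      } else {
        ids <- c(ids, b$building_id[i])
        xs <- c(xs, b$cx[i]); ys <- c(ys, b$cy[i])
        cls <- c(cls, as.integer(f > cut))
      }
    }
    tibble::tibble(building_id = ids, x = xs, y = ys, damage_class = cls)
  })
}

#' Place health facilities on host buildings
#'
#' Hospitals are hosted only by large (sparse-zone) buildings; pharmacies
#' preferentially by dense-block buildings; dialysis centers by sparse
#' small buildings. Each facility gets a distinct host. The recorded point
#' is the host centroid plus isotropic Gaussian geocoding jitter; with
#' probability `p_geocode_outside` the point is instead displaced 1–5 m
#' outside the footprint boundary. The gold label is the thresholded true
#' damage fraction of the host.
#'
#' @param city List with `buildings` (damage assigned) or a building tibble.
#' @param counts Named integer vector: `hospital`, `dialysis`, `pharmacy`.
#' @param err [error_params()].
#' @param seed Integer seed.
#' @param cut Gold-label damaged-fraction cut (strict >). Default 0.40.
#' @param city_name City label stamped on every facility.
#' @return Facility tibble (`facility_id`, `name`, `ftype`, `city`, `x`,
#'   `y`, `host_building_id`, `gold_label`).
#' @export
place_facilities <- function(city,
                             counts = c(hospital = 8, dialysis = 4,
                                        pharmacy = 150),
                             err = error_params(), seed = 1L, cut = 0.40,
                             city_name = "SimCity") {
  b <- if (is.data.frame(city)) city else city$buildings
  stopifnot("true_damage_fraction" %in% names(b))
  counts <- counts[intersect(names(counts), FACILITY_TYPES)]
  with_seed(sub_seed(seed, "facilities"), {
    large <- which(b$size_class == "large")
    dense <- which(b$zone == "dense")
    sparse_small <- which(b$zone == "sparse" & b$size_class == "small")

    pick <- function(pool, k, taken) {
      pool <- setdiff(pool, taken)
      if (length(pool) < k) {
        stop("not enough host buildings for the requested facility counts",
             call. = FALSE)
      }
      if (length(pool) == 1L) pool else sample(pool, k)
    }
    taken <- integer(0)
    hosts <- list()
    if (!is.na(counts["hospital"]) && counts["hospital"] > 0) {
      hosts$hospital <- pick(large, counts[["hospital"]], taken)
      taken <- c(taken, hosts$hospital)
    }
    if (!is.na(counts["dialysis"]) && counts["dialysis"] > 0) {
      pool <- if (length(setdiff(sparse_small, taken)) >= counts[["dialysis"]])
        sparse_small else c(sparse_small, dense)
      hosts$dialysis <- pick(pool, counts[["dialysis"]], taken)
      taken <- c(taken, hosts$dialysis)
    }
    if (!is.na(counts["pharmacy"]) && counts["pharmacy"] > 0) {
      pool <- if (length(setdiff(dense, taken)) >= counts[["pharmacy"]])
        dense else c(dense, sparse_small)
      hosts$pharmacy <- pick(pool, counts[["pharmacy"]], taken)
      taken <- c(taken, hosts$pharmacy)
    }

    rows <- list()
    idx <- 0L
    for (ft in names(hosts)) {
      for (m in seq_along(hosts[[ft]])) {
        i <- hosts[[ft]][m]
        idx <- idx + 1L
        px <- b$cx[i] + stats::rnorm(1, 0, err$geocode_sigma_m)
        py <- b$cy[i] + stats::rnorm(1, 0, err$geocode_sigma_m)
        if (stats::runif(1) < err$p_geocode_outside) {
          side <- sample(1:4, 1)
          d <- stats::runif(1, 1, 5)
          along_w <- stats::runif(1, -b$w[i] / 2, b$w[i] / 2)
          along_h <- stats::runif(1, -b$h[i] / 2, b$h[i] / 2)
          off <- switch(side,
            c(b$w[i] / 2 + d, along_h), c(-b$w[i] / 2 - d, along_h),
            c(along_w, b$h[i] / 2 + d), c(along_w, -b$h[i] / 2 - d))
          px <- b$cx[i] + off[1L]; py <- b$cy[i] + off[2L]
        }
        rows[[idx]] <- tibble::tibble(
          facility_id = sprintf("f%04d", idx),
          name = paste(capitalize(ft), m),
          ftype = ft, city = city_name, x = px, y = py,
          host_building_id = b$building_id[i],
          gold_label = as.integer(b$true_damage_fraction[i] > cut))
      }
    }
    dplyr::bind_rows(rows)
  })
}

#' Generate a complete synthetic city
#'
#' Runs the full generator chain — buildings, true damage field,
#' facilities, and both model dialects — and records the full parameter
#' set plus seed as provenance, so the city can be regenerated
#' bit-for-bit.
#'
#' @param n_buildings Number of buildings.
#' @param bounds City rectangle `c(xmin, ymin, xmax, ymax)` (m).
#' @param dense_fraction Fraction of buildings in dense blocks.
#' @param epicenter `c(x, y)` of peak damage (m); default the city centre.
#' @param d0 Damage decay scale (m).
#' @param noise_sd Damage-field noise SD.
#' @param destruction_cut Destroyed flag cut. Default 0.8.
#' @param counts Facility counts per type.
#' @param err [error_params()].
#' @param th [thresholds()]; supplies the damaged-fraction cut used for
#'   model-B classes and gold labels.
#' @param seed Integer master seed.
#' @param city_name Label for the generated city.
#' @return A `synthetic_city` list: `buildings`, `facilities`, `model_a`,
#'   `model_b`, `provenance`.
#' @examples
#' city <- generate_city(n_buildings = 120, counts = c(hospital = 2,
#'   dialysis = 1, pharmacy = 10), err = no_errors(), seed = 7)
#' nrow(city$model_a)
#' @export
generate_city <- function(n_buildings = 800,
                          bounds = c(0, 0, 2000, 2000),
                          dense_fraction = 0.5,
                          epicenter = NULL, d0 = 500, noise_sd = 0.1,
                          destruction_cut = 0.8,
                          counts = c(hospital = 8, dialysis = 4,
                                     pharmacy = 150),
                          err = error_params(), th = thresholds(),
                          seed = 1L, city_name = "SimCity") {
  if (is.null(epicenter)) {
    epicenter <- c(mean(bounds[c(1L, 3L)]), mean(bounds[c(2L, 4L)]))
  }
  b <- generate_buildings(n_buildings, bounds, dense_fraction, seed)
  b <- assign_true_damage(b, epicenter, d0, noise_sd, destruction_cut, seed)
  fac <- place_facilities(b, counts, err, seed,
                          cut = th$polygon_damage_cut, city_name = city_name)
  ma <- simulate_model_a(b, err, seed)
  mb <- simulate_model_b(b, err, seed, cut = th$polygon_damage_cut)
  structure(
    list(buildings = b, facilities = fac, model_a = ma, model_b = mb,
         provenance = list(
           n_buildings = n_buildings, bounds = bounds,
           dense_fraction = dense_fraction, epicenter = epicenter,
           d0 = d0, noise_sd = noise_sd, destruction_cut = destruction_cut,
           counts = as.list(counts), err = unclass(err),
           thresholds = unclass(th), seed = seed, city_name = city_name)),
    class = "synthetic_city")
}

#' @export
print.synthetic_city <- function(x, ...) {
  cat(sprintf(
    "synthetic city '%s': %d buildings (%d destroyed), %d facilities, %d polygons (A), %d centroids (B)\n",
    x$provenance$city_name, nrow(x$buildings), sum(x$buildings$destroyed),
    nrow(x$facilities), nrow(x$model_a), nrow(x$model_b)))
  invisible(x)
}

#' Write a synthetic city to a directory
#'
#' Serializes the city as plain-text files: `buildings.geojson`,
#' `model_a.geojson`, `model_b.geojson`, `facilities.csv`,
#' `provenance.json`. Metric coordinates are inverse-projected to WGS84
#' around `anchor` so the files exercise the same read path as real data.
#'
#' @param city A `synthetic_city`.
#' @param dir Output directory (created if missing).
#' @param anchor `c(lon, lat)` mapped to the metric origin.
#' @return `dir`, invisibly.
#' @export
write_city <- function(city, dir, anchor = c(36.16, 36.20)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  proj <- local_projection(anchor[1L], anchor[2L])
  b <- city$buildings
  bpoly <- tibble::tibble(
    building_id = b$building_id,
    geometry = lapply(seq_len(nrow(b)), function(i) list(building_ring(b[i, ]))),
    damage_fraction = b$true_damage_fraction)
  write_damage_polygons(bpoly, file.path(dir, "buildings.geojson"), proj)
  write_damage_polygons(city$model_a, file.path(dir, "model_a.geojson"), proj)
  write_damage_centroids(city$model_b, file.path(dir, "model_b.geojson"), proj)
  fac <- from_metric(city$facilities, proj)
  write_facilities(fac, file.path(dir, "facilities.csv"))
  prov <- city$provenance
  prov$anchor <- anchor
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
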