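# Readers, writers, validation and deduplication for the three input
# families: damage polygons (footprint + damaged fraction), damage centroids
# (point + binary class), and health facilities (typed lon/lat points).
#
# Supported formats are GeoJSON and CSV. GeoPackage requires GDAL bindings
# that this package deliberately does not depend on; convert with e.g.
# `ogr2ogr -f GeoJSON out.geojson in.gpkg` before reading.

FACILITY_TYPES <- c("hospital", "dialysis", "pharmacy")

read_geojson <- function(path) {
  if (grepl("\\.gpkg$", path, ignore.case = TRUE)) {
    stop("GeoPackage is not supported (no GDAL bindings); ",
         "convert to GeoJSON first", call. = FALSE)
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection: ", path,
                                 call. = FALSE)
  gj
}

# GeoJSON polygon coordinates -> list of ring matrices
gj_rings <- function(coords) {
  lapply(coords, function(ring) {
    m <- do.call(rbind, lapply(ring, function(p) c(p[[1L]], p[[2L]])))
    ring_close(m)
  })
}

#' Read building damage polygons
#'
#' Reads the polygon damage dialect: one feature per building footprint with
#' a numeric damaged-fraction attribute. MultiPolygon features are split
#' into their parts, each part keeping the parent's damage value with the id
#' suffixed `_p1`, `_p2`, ... Damage values are unit-sniffed: when the
#' dataset maximum exceeds 1.5 the values are taken as percentages and
#' divided by 100. Self-intersecting rings are repaired by splitting at the
#' crossing into simple lobes; irreparable (zero-area) geometries are
#' rejected and logged.
#'
#' @param path GeoJSON file of Polygon/MultiPolygon features.
#' @param damage_field Name of the feature property holding the damage
#'   value. Default `"damage"`.
#' @param id_field Property holding the building id; features without it
#'   get their 1-based index.
#' @param proj Optional [local_projection()]; when supplied, coordinates are
#'   assumed WGS84 lon/lat and are projected to meters.
#' @return A tibble with columns `building_id`, `geometry` (list of ring
#'   lists, meters), `damage_fraction`; rejected features are recorded in
#'   the `"rejected"` attribute with a reason each.
#' @export
read_damage_polygons <- function(path, damage_field = "damage",
                                 id_field = "building_id", proj = NULL) {
  gj <- read_geojson(path)
  feats <- gj$features
  if (length(feats) == 0L) {
    warning("empty feature collection: ", path, call. = FALSE)
    return(empty_polygons())
  }
  ids <- character(); geoms <- list(); dmg <- numeric()
  rej_id <- character(); rej_why <- character()
  for (k in seq_along(feats)) {
    f <- feats[[k]]
    id <- as.character(f$properties[[id_field]] %||% k)
    val <- f$properties[[damage_field]]
    if (is.null(val) || !is.numeric(val) || is.na(val)) {
      stop("feature ", id, ": missing or non-numeric damage field '",
           damage_field, "'", call. = FALSE)
    }
    gtype <- f$geometry$type
    parts <- switch(gtype,
      Polygon = list(gj_rings(f$geometry$coordinates)),
      MultiPolygon = lapply(f$geometry$coordinates, gj_rings),
      stop("feature ", id, ": geometry type ", gtype,
           " is not polygonal", call. = FALSE))
    part_ids <- if (length(parts) > 1L) paste0(id, "_p", seq_along(parts)) else id
    for (p in seq_along(parts)) {
      geom <- parts[[p]]
      if (!ring_is_simple(geom[[1L]])) {
        lobes <- ring_repair(geom[[1L]])
        if (length(lobes) == 0L) {
          rej_id <- c(rej_id, part_ids[p])
          rej_why <- c(rej_why, "irreparable geometry")
          next
        }
        lobe_ids <- if (length(lobes) > 1L) {
          paste0(part_ids[p], "_r", seq_along(lobes))
        } else part_ids[p]
        for (l in seq_along(lobes)) {
          ids <- c(ids, lobe_ids[l]); geoms <- c(geoms, list(list(lobes[[l]])))
          dmg <- c(dmg, val)
        }
      } else if (poly_area(geom) <= 0) {
        rej_id <- c(rej_id, part_ids[p])
        rej_why <- c(rej_why, "empty geometry")
      } else {
        ids <- c(ids, part_ids[p]); geoms <- c(geoms, list(geom))
        dmg <- c(dmg, val)
      }
    }
  }
  if (anyDuplicated(ids)) {
    stop("duplicate building_id: ", ids[duplicated(ids)][1L], call. = FALSE)
  }
  if (length(dmg) && max(dmg) > 1.5) {
    message("damage values look like percentages (max ", max(dmg),
            "); dividing by 100")
    dmg <- dmg / 100
  }
  if (any(dmg < 0 | dmg > 1)) {
    stop("damage fractions outside [0, 1] after unit normalization",
         call. = FALSE)
  }
  if (!is.null(proj)) geoms <- lapply(geoms, project_geom, proj = proj)
  out <- tibble::tibble(building_id = ids, geometry = geoms,
                        damage_fraction = dmg)
  attr(out, "rejected") <- tibble::tibble(building_id = rej_id, reason = rej_why)
  out
}

empty_polygons <- function() {
  out <- tibble::tibble(building_id = character(), geometry = list(),
                        damage_fraction = numeric())
  attr(out, "rejected") <- tibble::tibble(building_id = character(),
                                          reason = character())
  out
}

project_geom <- function(geom, proj) lapply(geom, to_metric, proj = proj)

#' Read building damage centroids
#'
#' Reads the centroid damage dialect: one point per building with a binary
#' damage class (1 = major damage/destroyed). Accepts GeoJSON Point
#' features or a CSV with `building_id`, `lon`, `lat` and the class/score
#' column. When a `score_field` and `score_threshold` are supplied the
#' class is derived as `score >= score_threshold`.
#'
#' @param path GeoJSON or CSV file.
#' @param class_field Property/column with the binary class. Default
#'   `"damage_class"`.
#' @param score_field,score_threshold Optional continuous score column and
#'   the city-specific threshold resolving it to a class.
#' @param id_field Property holding the building id.
#' @param proj Optional [local_projection()] to project lon/lat to meters;
#'   without it, coordinates are taken to be already metric `x`/`y`.
#' @return Tibble with `building_id`, `x`, `y`, `damage_class` and, when
#'   present, `score`.
#' @export
read_damage_centroids <- function(path, class_field = "damage_class",
                                  score_field = NULL, score_threshold = NULL,
                                  id_field = "building_id", proj = NULL) {
  is_csv <- grepl("\\.csv$", path, ignore.case = TRUE)
  if (is_csv) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    ids <- as.character(df[[id_field]] %||% seq_len(nrow(df)))
    lon <- df$lon %||% df$x; lat <- df$lat %||% df$y
    score <- if (!is.null(score_field)) df[[score_field]] else NULL
    cls <- df[[class_field]]
  } else {
    gj <- read_geojson(path)
    feats <- gj$features
    ids <- character(length(feats)); lon <- lat <- numeric(length(feats))
    cls <- rep(NA_real_, length(feats)); score <- rep(NA_real_, length(feats))
    for (k in seq_along(feats)) {
      f <- feats[[k]]
      if (!identical(f$geometry$type, "Point")) {
        stop("feature ", k, ": geometry type ", f$geometry$type,
             " is not Point", call. = FALSE)
      }
      ids[k] <- as.character(f$properties[[id_field]] %||% k)
      lon[k] <- f$geometry$coordinates[[1L]]
      lat[k] <- f$geometry$coordinates[[2L]]
      cls[k] <- f$properties[[class_field]] %||% NA_real_
      if (!is.null(score_field)) {
        score[k] <- f$properties[[score_field]] %||% NA_real_
      }
    }
    if (is.null(score_field)) score <- NULL
  }
  if (anyDuplicated(ids)) {
    stop("duplicate building_id: ", ids[duplicated(ids)][1L], call. = FALSE)
  }
  if (!is.null(score_field)) {
    if (is.null(score_threshold)) {
      stop("score_field supplied without score_threshold", call. = FALSE)
    }
    cls <- as.integer(score >= score_threshold)
  } else {
    if (!all(cls %in% c(0, 1))) {
      stop("damage class values outside {0, 1}; supply score_field and ",
           "score_threshold for continuous scores", call. = FALSE)
    }
    cls <- as.integer(cls)
  }
  if (!is.null(proj)) {
    xy <- to_metric(cbind(lon, lat), proj)
  } else {
    xy <- cbind(lon, lat)
  }
  out <- tibble::tibble(building_id = ids, x = xy[, 1L], y = xy[, 2L],
                        damage_class = cls)
  if (!is.null(score_field)) out$score <- as.numeric(score)
  out
}

#' Read health facility locations
#'
#' Accepts the CSV dialect (columns `facility_id`, `name`, `ftype`, `city`,
#' `lon`, `lat`, optional `gold_label`) or GeoJSON Point features with the
#' same properties. Facility types must be one of `hospital`, `dialysis`,
#' `pharmacy`; coordinates are validated against WGS84 ranges.
#'
#' @param path CSV or GeoJSON file.
#' @param proj Optional [local_projection()]; when `NULL` one is fitted to
#'   the data centroid. Projected coordinates are stored in `x`/`y` next to
#'   the geographic `lon`/`lat`.
#' @return Tibble of facilities with both coordinate systems populated; the
#'   projection used is in the `"projection"` attribute.
#' @export
read_facilities <- function(path, proj = NULL) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("name", "ftype", "city", "lon", "lat")
    if (!all(need %in% names(df))) {
      stop("facility CSV must have columns ",
           paste(need, collapse = ", "), call. = FALSE)
    }
    df$facility_id <- as.character(df$facility_id %||% sprintf("f%04d", seq_len(nrow(df))))
  } else {
    gj <- read_geojson(path)
    feats <- gj$features
    df <- do.call(rbind, lapply(seq_along(feats), function(k) {
      f <- feats[[k]]
      if (!identical(f$geometry$type, "Point")) {
        stop("feature ", k, " is not a Point", call. = FALSE)
      }
      p <- f$properties
      data.frame(
        facility_id = as.character(p$facility_id %||% sprintf("f%04d", k)),
        name = as.character(p$name %||% ""),
        ftype = as.character(p$ftype %||% ""),
        city = as.character(p$city %||% ""),
        lon = f$geometry$coordinates[[1L]],
        lat = f$geometry$coordinates[[2L]],
        gold_label = if (is.null(p$gold_label)) NA_integer_ else as.integer(p$gold_label),
        stringsAsFactors = FALSE)
    }))
  }
  if (any(abs(df$lat) > 90 | abs(df$lon) > 180 | !is.finite(df$lat) |
          !is.finite(df$lon))) {
    stop("lat/lon out of range", call. = FALSE)
  }
  bad <- setdiff(unique(df$ftype), FACILITY_TYPES)
  if (length(bad)) {
    stop("unknown facility type(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(df$gold_label)) df$gold_label <- NA_integer_
  if (is.null(proj)) proj <- projection_for(df$lon, df$lat)
  out <- to_metric(tibble::as_tibble(df), proj)
  out[c("facility_id", "name", "ftype", "city", "lon", "lat", "x", "y",
        "gold_label")]
}

#' Normalize a facility name for duplicate matching
#'
#' Lowercases, strips punctuation, collapses whitespace.
#' @param x Character vector of names.
#' @return Normalized names.
#' @export
normalize_name <- function(x) {
  x <- tolower(x)
  x <- gsub("[[:punct:]]", " ", x)
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

#' Remove duplicate facilities
#'
#' Two records are duplicates when their normalized names match exactly and
#' their projected distance is strictly below `radius_m`. Duplication is
#' transitive (connected components); each component keeps its
#' first-encountered record.
#'
#' @param facilities Facility tibble with projected `x`/`y` (see
#'   [read_facilities()]).
#' @param radius_m Distance guard in meters. Default 10.
#' @param name_normalizer Function mapping names to comparison keys.
#' @return List with `kept` (deduplicated tibble) and `removed` (tibble of
#'   `removed_id`, `kept_id` pairs).
#' @export
deduplicate_facilities <- function(facilities, radius_m = 10,
                                   name_normalizer = normalize_name) {
  stopifnot(radius_m > 0)
  n <- nrow(facilities)
  if (n == 0L) {
    return(list(kept = facilities,
                removed = tibble::tibble(removed_id = character(),
                                         kept_id = character())))
  }
  key <- name_normalizer(facilities$name)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (g in split(seq_len(n), key)) {
    if (length(g) < 2L) next
    for (a in seq_along(g)[-length(g)]) for (b in (a + 1L):length(g)) {
      i <- g[a]; j <- g[b]
      d <- sqrt((facilities$x[i] - facilities$x[j])^2 +
                (facilities$y[i] - facilities$y[j])^2)
      if (d < radius_m) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  root <- vapply(seq_len(n), find, 0L)
  keep <- root == seq_len(n)
  removed <- tibble::tibble(
    removed_id = facilities$facility_id[!keep],
    kept_id = facilities$facility_id[root[!keep]])
  list(kept = facilities[keep, ], removed = removed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- writers ----------------------------------------------------------

#' Write damage polygons as GeoJSON
#'
#' @param polygons Tibble from [read_damage_polygons()] or
#'   [simulate_model_a()].
#' @param path Output file.
#' @param proj Optional [local_projection()]; when supplied, metric
#'   coordinates are inverse-projected to WGS84 before writing.
#' @return `path`, invisibly.
#' @export
write_damage_polygons <- function(polygons, path, proj = NULL) {
  feats <- lapply(seq_len(nrow(polygons)), function(k) {
    geom <- polygons$geometry[[k]]
    if (!is.null(proj)) geom <- lapply(geom, from_metric, proj = proj)
    coords <- lapply(geom, function(ring) {
      ring <- ring_close(ring)
      lapply(seq_len(nrow(ring)), function(i) c(ring[i, 1L], ring[i, 2L]))
    })
    list(type = "Feature",
         properties = list(building_id = polygons$building_id[k],
                           damage = polygons$damage_fraction[k]),
         geometry = list(type = "Polygon", coordinates = coords))
  })
  write_feature_collection(feats, path)
}

#' Write damage centroids as GeoJSON
#'
#' @inheritParams write_damage_polygons
#' @param centroids Tibble from [read_damage_centroids()] or
#'   [simulate_model_b()].
#' @return `path`, invisibly.
#' @export
write_damage_centroids <- function(centroids, path, proj = NULL) {
  xy <- cbind(centroids$x, centroids$y)
  if (!is.null(proj)) xy <- from_metric(xy, proj)
  feats <- lapply(seq_len(nrow(centroids)), function(k) {
    list(type = "Feature",
         properties = list(building_id = centroids$building_id[k],
                           damage_class = centroids$damage_class[k]),
         geometry = list(type = "Point",
                         coordinates = c(xy[k, 1L], xy[k, 2L])))
  })
  write_feature_collection(feats, path)
}

write_feature_collection <- function(features, path) {
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Write facilities as CSV
#'
#' @param facilities Facility tibble.
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_facilities <- function(facilities, path) {
  cols <- intersect(c("facility_id", "name", "ftype", "city", "lon", "lat",
                      "gold_label"), names(facilities))
  utils::write.csv(as.data.frame(facilities[cols]), path, row.names = FALSE)
  invisible(path)
}

#' Read an S1-style per-facility estimates table
#'
#' Reads a flat per-facility table carrying both models' building-level
#' estimates alongside facility metadata — the layout of a supplementary
#' "facility locations and damage estimates" spreadsheet exported to CSV.
#' Column names are mapped via `col_map`, so any layout can be adapted
#' without editing the file.
#'
#' @param path CSV file.
#' @param col_map Named character vector mapping canonical names
#'   (`facility_id`, `name`, `ftype`, `city`, `lon`, `lat`, `gold_label`,
#'   `model_a_fraction`, `model_b_class`) to the file's column names.
#'   Identity mapping by default.
#' @return Tibble with canonical column names (missing optional columns are
#'   NA).
#' @export
read_facility_table <- function(path, col_map = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  canonical <- c("facility_id", "name", "ftype", "city", "lon", "lat",
                 "gold_label", "model_a_fraction", "model_b_class")
  if (!is.null(col_map)) {
    for (nm in names(col_map)) {
      if (!col_map[[nm]] %in% names(df)) {
        stop("mapped column '", col_map[[nm]], "' not in file", call. = FALSE)
      }
      df[[nm]] <- df[[col_map[[nm]]]]
    }
  }
  for (nm in canonical) if (is.null(df[[nm]])) df[[nm]] <- NA
  out <- tibble::as_tibble(df[canonical])
  if (!all(stats::na.omit(out$model_b_class) %in% c(0, 1))) {
    stop("model_b_class values outside {0, 1}", call. = FALSE)
  }
  out
}
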