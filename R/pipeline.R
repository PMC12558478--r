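# End-to-end orchestration: read (or simulate) -> overlay and/or aggregate
# -> evaluate -> report bundle, plus the synthetic benchmark sweep.

#' Build and validate a pipeline run configuration
#'
#' Either the three input paths (`model_a`, `model_b`, `facilities`) or a
#' `synthetic` parameter list (arguments to [generate_city()]) must be
#' supplied. Paths are checked at validation time, before any computation.
#'
#' @param model_a,model_b,facilities Input file paths (GeoJSON / CSV; see
#'   the readers). Ignored in synthetic mode.
#' @param synthetic Optional named list of [generate_city()] arguments;
#'   when present the pipeline runs on a generated city.
#' @param out_dir Output directory for the report bundle; `NULL` for no
#'   file output.
#' @param method `"both"`, `"individual"` or `"aggregated"`.
#' @param th [thresholds()].
#' @param strata Stratification columns for the metrics table.
#' @param exclude_no_data Drop facilities lacking coverage (`no_data`)
#'   from either model before evaluation (the published analysis excluded
#'   facilities without damage data from both models). Default TRUE.
#' @param dedup_radius_m Duplicate-facility collapse radius (m).
#' @param seed Integer seed (synthetic mode and any resampling).
#' @param damage_field,class_field Attribute names for the two readers.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(model_a = NULL, model_b = NULL, facilities = NULL,
                       synthetic = NULL, out_dir = NULL,
                       method = c("both", "individual", "aggregated"),
                       th = thresholds(), strata = c("ftype", "city"),
                       exclude_no_data = TRUE, dedup_radius_m = 10,
                       seed = 1L, damage_field = "damage",
                       class_field = "damage_class") {
  method <- match.arg(method)
  stopifnot(inherits(th, "damage_thresholds"))
  if (is.null(synthetic)) {
    for (p in c(model_a = model_a, model_b = model_b,
                facilities = facilities)) {
      if (is.null(p) || !file.exists(p)) {
        stop("missing input path: ", p %||% "(not set)", call. = FALSE)
      }
    }
  }
  structure(list(model_a = model_a, model_b = model_b,
                 facilities = facilities, synthetic = synthetic,
                 out_dir = out_dir, method = method, th = th,
                 strata = strata, exclude_no_data = exclude_no_data,
                 dedup_radius_m = dedup_radius_m, seed = as.integer(seed),
                 damage_field = damage_field, class_field = class_field),
            class = "run_config")
}

#' Run the full damage-report pipeline
#'
#' Reads (or generates) the inputs, produces individual and/or aggregated
#' facility damage calls for both models, evaluates agreement and (when
#' gold labels exist) accuracy, and writes a deterministic report bundle:
#' `calls.csv`, `summary_table.csv`, `metrics_<method>.csv`,
#' `grid_model_[ab].geojson` (aggregated method) and `provenance.json`.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `facilities`, `calls` (stacked tibble),
#'   `report` (individual summary table), `metrics` (per method),
#'   `grids` (classified grids per model) and `provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  th <- config$th

  if (!is.null(config$synthetic)) {
    city <- do.call(generate_city,
                    c(config$synthetic, list(th = th, seed = config$seed)))
    fac <- city$facilities
    fac$gold_label <- as.integer(fac$gold_label)
    polygons <- city$model_a
    centroids <- city$model_b
    provenance <- city$provenance
  } else {
    fac <- read_facilities(config$facilities)
    proj <- attr(fac, "projection")
    polygons <- read_damage_polygons(config$model_a,
                                     damage_field = config$damage_field,
                                     proj = proj)
    centroids <- read_damage_centroids(config$model_b,
                                       class_field = config$class_field,
                                       proj = proj)
    provenance <- list(model_a = config$model_a, model_b = config$model_b,
                       facilities = config$facilities,
                       projection = unclass(proj))
  }
  dd <- deduplicate_facilities(fac, config$dedup_radius_m)
  fac <- dd$kept

  calls <- list(); metrics <- list(); grids <- list(); report <- NULL

  if (config$method %in% c("both", "individual")) {
    ca <- overlay_model_a(fac, polygons, th)
    cb <- overlay_model_b(fac, centroids, th)
    keep <- fac$facility_id
    if (config$exclude_no_data) {
      drop <- union(ca$facility_id[ca$basis == "no_data"],
                    cb$facility_id[cb$basis == "no_data"])
      keep <- setdiff(keep, drop)
    }
    fi <- fac[fac$facility_id %in% keep, ]
    cai <- ca[ca$facility_id %in% keep, ]
    cbi <- cb[cb$facility_id %in% keep, ]
    report <- individual_report(cai, cbi, fi)
    metrics$individual <- stratified_metrics(cai, cbi, fi,
                                             strata = config$strata,
                                             alpha = th$alpha)
    calls$individual <- dplyr::bind_rows(ca, cb)
  }

  if (config$method %in% c("both", "aggregated")) {
    agg <- aggregated_calls(fac, polygons, centroids, th)
    grids <- agg$grids
    keep <- fac$facility_id
    if (config$exclude_no_data) {
      drop <- union(
        agg$calls_a$facility_id[agg$calls_a$basis == "no_data"],
        agg$calls_b$facility_id[agg$calls_b$basis == "no_data"])
      keep <- setdiff(keep, drop)
    }
    fi <- fac[fac$facility_id %in% keep, ]
    metrics$aggregated <- stratified_metrics(
      agg$calls_a[agg$calls_a$facility_id %in% keep, ],
      agg$calls_b[agg$calls_b$facility_id %in% keep, ],
      fi, strata = config$strata, alpha = th$alpha)
    calls$aggregated <- dplyr::bind_rows(agg$calls_a, agg$calls_b)
  }

  all_calls <- dplyr::bind_rows(calls)
  result <- list(facilities = fac, calls = all_calls, report = report,
                 metrics = metrics, grids = grids,
                 removed_duplicates = dd$removed,
                 provenance = c(provenance,
                                list(thresholds = unclass(th),
                                     method = config$method,
                                     exclude_no_data = config$exclude_no_data,
                                     seed = config$seed,
                                     package_version =
                                       as.character(utils::packageVersion("facdamage")))))
  if (!is.null(config$out_dir)) write_bundle(result, config$out_dir)
  invisible(result)
}

# aggregated-method calls for both models on a shared bounding region
aggregated_calls <- function(fac, polygons, centroids, th) {
  pts_a <- t(vapply(polygons$geometry, poly_centroid, numeric(2)))
  xs <- c(pts_a[, 1L], centroids$x, fac$x)
  ys <- c(pts_a[, 2L], centroids$y, fac$y)
  bounds <- c(min(xs), min(ys), max(xs), max(ys))
  grid <- make_hex_grid(bounds, th$cell_area_km2)
  ga <- aggregate_damage(polygons, grid, th)
  gb <- aggregate_damage(centroids, grid, th)
  qa <- quartile_classify(ga, th)
  qb <- quartile_classify(gb, th)
  cut_a <- qa$breaks[[th$quartile_cut]]
  cut_b <- qb$breaks[[th$quartile_cut]]
  list(calls_a = facility_cell_calls(fac, qa$grid, cut_a, "A"),
       calls_b = facility_cell_calls(fac, qb$grid, cut_b, "B"),
       grids = list(A = qa, B = qb))
}

write_bundle <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(result$calls),
                   file.path(out_dir, "calls.csv"), row.names = FALSE)
  if (!is.null(result$report)) {
    utils::write.csv(as.data.frame(result$report),
                     file.path(out_dir, "summary_table.csv"),
                     row.names = FALSE)
  }
  for (m in names(result$metrics)) {
    utils::write.csv(as.data.frame(result$metrics[[m]]),
                     file.path(out_dir, paste0("metrics_", m, ".csv")),
                     row.names = FALSE)
  }
  for (m in names(result$grids)) {
    g <- result$grids[[m]]$grid
    feats <- lapply(which(g$building_count > 0), function(k) {
      ring <- ring_close(g$geometry[[k]])
      coords <- list(lapply(seq_len(nrow(ring)),
                            function(i) c(ring[i, 1L], ring[i, 2L])))
      list(type = "Feature",
           properties = list(cell_id = g$cell_id[k],
                             building_count = g$building_count[k],
                             damaged_count = g$damaged_count[k],
                             proportion = g$proportion[k],
                             quartile = g$quartile[k]),
           geometry = list(type = "Polygon", coordinates = coords))
    })
    write_feature_collection(
      feats, file.path(out_dir, paste0("grid_model_",
                                       tolower(m), ".geojson")))
  }
  jsonlite::write_json(result$provenance,
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' Synthetic benchmark over error-parameter settings
#'
#' For each row of `err_grid` and each seed, generates a city, runs the
#' individual (and optionally aggregated) overlays for both model
#' dialects, and scores sensitivity, specificity and inter-model kappa
#' against the generator's gold labels. Returns the raw per-run table and
#' a summary with Monte-Carlo standard errors.
#'
#' @param err_grid Data frame whose columns are [error_params()] arguments;
#'   one benchmark point per row. Unspecified parameters default to 0.
#' @param n_seeds Seeds per point (1, 2, ..., `n_seeds`, offset by
#'   `base_seed`).
#' @param city_args Named list of [generate_city()] arguments shared by all
#'   runs (e.g. `n_buildings`, `counts`).
#' @param th [thresholds()].
#' @param methods Character subset of `c("individual", "aggregated")`.
#' @param base_seed Added to each seed index.
#' @return List with `raw` (one row per run x method x model) and
#'   `summary` (means and MC standard errors per benchmark point).
#' @export
run_synthetic_benchmark <- function(err_grid = data.frame(p_destroyed_miss = c(0, 0.5, 1)),
                                    n_seeds = 20L,
                                    city_args = list(n_buildings = 300,
                                                     counts = c(hospital = 4,
                                                                dialysis = 2,
                                                                pharmacy = 30)),
                                    th = thresholds(),
                                    methods = "individual",
                                    base_seed = 0L) {
  stopifnot(n_seeds >= 1)
  zero <- list(p_merge = 0, p_multi_centroid = 0, p_destroyed_miss = 0,
               geocode_sigma_m = 0, p_geocode_outside = 0)
  rows <- list()
  for (r in seq_len(nrow(err_grid))) {
    ep <- zero
    for (nm in names(err_grid)) ep[[nm]] <- err_grid[[nm]][r]
    err <- do.call(error_params, ep)
    for (s in seq_len(n_seeds)) {
      seed <- base_seed + s
      city <- do.call(generate_city,
                      c(city_args, list(err = err, th = th, seed = seed)))
      fac <- city$facilities
      score <- function(calls, method, model) {
        cc <- confusion(calls$damaged, fac$gold_label)
        acc <- sens_spec(cc, th$alpha)
        tibble::tibble(point = r, seed = seed, method = method,
                       model = model, sensitivity = acc$sensitivity,
                       specificity = acc$specificity)
      }
      if ("individual" %in% methods) {
        ca <- overlay_model_a(fac, city$model_a, th)
        cb <- overlay_model_b(fac, city$model_b, th)
        kp <- cohens_kappa(ca$damaged, cb$damaged)
        ra <- score(ca, "individual", "A"); ra$kappa <- kp$kappa
        rb <- score(cb, "individual", "B"); rb$kappa <- kp$kappa
        rows <- c(rows, list(ra, rb))
      }
      if ("aggregated" %in% methods) {
        agg <- aggregated_calls(fac, city$model_a, city$model_b, th)
        kp <- cohens_kappa(agg$calls_a$damaged, agg$calls_b$damaged)
        ra <- score(agg$calls_a, "aggregated", "A"); ra$kappa <- kp$kappa
        rb <- score(agg$calls_b, "aggregated", "B"); rb$kappa <- kp$kappa
        rows <- c(rows, list(ra, rb))
      }
    }
  }
  raw <- dplyr::bind_rows(rows)
  for (nm in names(err_grid)) {
    raw[[nm]] <- err_grid[[nm]][raw$point]
  }
  mc_se <- function(v) stats::sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v)))
  summary <- dplyr::summarise(
    dplyr::group_by(raw, .data$point, .data$method, .data$model),
    dplyr::across(dplyr::all_of(names(err_grid)), dplyr::first),
    mean_sensitivity = mean(.data$sensitivity, na.rm = TRUE),
    se_sensitivity = mc_se(.data$sensitivity),
    mean_specificity = mean(.data$specificity, na.rm = TRUE),
    se_specificity = mc_se(.data$specificity),
    mean_kappa = mean(.data$kappa, na.rm = TRUE),
    n_runs = dplyr::n(), .groups = "drop")
  list(raw = raw, summary = summary)
}
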