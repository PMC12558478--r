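# Spatially aggregated damage: hexagonal binning at fixed cell area,
# per-cell damaged proportion, quartile classification, and facility
# assignment by the third-quartile rule.

#' Build a hexagonal grid of fixed cell area
#'
#' Tiles the bounding rectangle with flat-topped regular hexagons of area
#' `cell_area_km2`, edge length `a = sqrt(2 A / (3 sqrt(3)))` with A in
#' m^2. The grid is anchored at the lower-left corner of `bounds` and
#' extends one cell beyond each side so every point of the bounds falls in
#' exactly one cell (Voronoi assignment to the nearest hexagon centre;
#' boundary ties resolve to the lowest `cell_id`).
#'
#' @param bounds `c(xmin, ymin, xmax, ymax)` in meters.
#' @param cell_area_km2 Cell area in km^2. Default 0.125.
#' @return Tibble of cells: `cell_id`, `ci`, `cj` (lattice indices), `cx`,
#'   `cy`, `geometry` (hexagon ring). The edge length is stored in the
#'   `"edge"` attribute, the anchor in `"anchor"`.
#' @examples
#' g <- make_hex_grid(c(0, 0, 1000, 1000))
#' attr(g, "edge")   # ~219.3 m for 0.125 km^2
#' @export
make_hex_grid <- function(bounds, cell_area_km2 = 0.125) {
  stopifnot(bounds[3L] > bounds[1L], bounds[4L] > bounds[2L],
            cell_area_km2 > 0)
  area_m2 <- cell_area_km2 * 1e6
  a <- sqrt(2 * area_m2 / (3 * sqrt(3)))
  dx <- 1.5 * a          # column spacing
  dy <- sqrt(3) * a      # row spacing
  x0 <- bounds[1L]; y0 <- bounds[2L]
  ci <- seq(-1L, ceiling((bounds[3L] - x0) / dx) + 1L)
  cj <- seq(-2L, ceiling((bounds[4L] - y0) / dy) + 1L)
  grid <- expand.grid(cj = cj, ci = ci)  # cj fastest: ids ordered by column
  grid$cx <- x0 + grid$ci * dx
  grid$cy <- y0 + grid$cj * dy + ifelse(grid$ci %% 2L == 0L, 0, dy / 2)
  ang <- seq(0, 300, by = 60) * pi / 180
  out <- tibble::tibble(
    cell_id = seq_len(nrow(grid)),
    ci = grid$ci, cj = grid$cj, cx = grid$cx, cy = grid$cy,
    geometry = lapply(seq_len(nrow(grid)), function(k) {
      ring_close(cbind(grid$cx[k] + a * cos(ang), grid$cy[k] + a * sin(ang)))
    }))
  attr(out, "edge") <- a
  attr(out, "anchor") <- c(x0, y0)
  out
}

#' Assign points to hexagonal grid cells
#'
#' Voronoi assignment: each point belongs to the cell with the nearest
#' centre (equivalent to point-in-hexagon for a hexagonal lattice). Exact
#' ties go to the lowest `cell_id`. Points beyond the grid (possible only
#' for inputs outside the bounds the grid was built for) are attached to
#' the nearest cell with a warning.
#'
#' @param x,y Numeric vectors of point coordinates (meters).
#' @param grid Tibble from [make_hex_grid()].
#' @return Integer vector of `cell_id`s.
#' @export
assign_cells <- function(x, y, grid) {
  a <- attr(grid, "edge")
  anchor <- attr(grid, "anchor")
  dx <- 1.5 * a; dy <- sqrt(3) * a
  key <- function(ci, cj) paste(ci, cj)
  lookup <- stats::setNames(grid$cell_id, key(grid$ci, grid$cj))

  n <- length(x)
  out <- integer(n)
  ci0 <- round((x - anchor[1L]) / dx)
  for (i in seq_len(n)) {
    best_id <- NA_integer_; best_d <- Inf
    for (ci in (ci0[i] - 1L):(ci0[i] + 1L)) {
      off <- if (ci %% 2L == 0L) 0 else dy / 2
      cj0 <- round((y[i] - anchor[2L] - off) / dy)
      for (cj in (cj0 - 1L):(cj0 + 1L)) {
        id <- lookup[key(ci, cj)]
        if (is.na(id)) next
        cxy <- c(anchor[1L] + ci * dx, anchor[2L] + cj * dy + off)
        d <- (cxy[1L] - x[i])^2 + (cxy[2L] - y[i])^2
        if (d < best_d - 1e-9 || (abs(d - best_d) <= 1e-9 && id < best_id)) {
          best_d <- d; best_id <- id
        }
      }
    }
    if (is.na(best_id)) {
      warning("point outside the grid; assigned to nearest cell",
              call. = FALSE)
      d <- (grid$cx - x[i])^2 + (grid$cy - y[i])^2
      best_id <- grid$cell_id[which.min(d)]
    }
    out[i] <- best_id
  }
  out
}

#' Aggregate building damage onto a grid
#'
#' Counts buildings and damaged buildings per cell and derives the damaged
#' proportion. The representative point of a building is its footprint
#' centroid for the polygon dialect and the point itself for the centroid
#' dialect; each building contributes to exactly one cell.
#'
#' @param objects Damage polygon tibble (with `geometry` and
#'   `damage_fraction`) or damage centroid tibble (with `x`, `y`,
#'   `damage_class`).
#' @param grid Tibble from [make_hex_grid()].
#' @param th [thresholds()].
#' @return `grid` with `building_count`, `damaged_count` and `proportion`
#'   (NA for empty cells) added.
#' @export
aggregate_damage <- function(objects, grid, th = thresholds()) {
  if ("geometry" %in% names(objects)) {
    pts <- t(vapply(objects$geometry, poly_centroid, numeric(2)))
    dmg <- classify_polygon(objects$damage_fraction, th$polygon_damage_cut)
  } else {
    pts <- cbind(objects$x, objects$y)
    dmg <- classify_centroid(objects$damage_class)
  }
  cell <- assign_cells(pts[, 1L], pts[, 2L], grid)
  grid$building_count <- as.integer(
    table(factor(cell, levels = grid$cell_id)))
  grid$damaged_count <- as.integer(
    table(factor(cell[dmg], levels = grid$cell_id)))
  grid$proportion <- ifelse(grid$building_count > 0,
                            grid$damaged_count / grid$building_count,
                            NA_real_)
  grid
}

#' Classify cells into damage quartiles
#'
#' Quartile breaks are computed over the damaged proportions of non-empty
#' cells (linear interpolation between order statistics by default) and
#' each non-empty cell is labelled Q1–Q4; empty cells are labelled
#' `"empty"`. Cells exactly on a break go to the lower quartile, matching
#' the strictly-greater facility rule.
#'
#' @param grid Output of [aggregate_damage()].
#' @param th [thresholds()]; `quantile_type` selects the estimator.
#' @return List with `grid` (quartile column added), `breaks` (Q1–Q3
#'   values) and `q3_value`.
#' @export
quartile_classify <- function(grid, th = thresholds()) {
  props <- grid$proportion[!is.na(grid$proportion)]
  if (length(props) < 4L) {
    stop("need at least 4 non-empty cells for quartiles", call. = FALSE)
  }
  brk <- stats::quantile(props, c(0.25, 0.5, 0.75),
                         type = th$quantile_type, names = FALSE)
  lab <- rep("empty", nrow(grid))
  ok <- !is.na(grid$proportion)
  p <- grid$proportion[ok]
  lab[ok] <- ifelse(p <= brk[1L], "Q1",
             ifelse(p <= brk[2L], "Q2",
             ifelse(p <= brk[3L], "Q3", "Q4")))
  grid$quartile <- lab
  list(grid = grid,
       breaks = stats::setNames(brk, c("Q1", "Q2", "Q3")),
       q3_value = brk[3L])
}

#' Aggregated facility damage calls
#'
#' A facility is called likely-damaged when the damaged proportion of the
#' cell containing it strictly exceeds the chosen quartile break (the
#' third quartile by default). Facilities in empty cells are undamaged
#' with basis `no_data`.
#'
#' @param facilities Facility tibble with metric `x`/`y`.
#' @param grid Classified grid (from [quartile_classify()]`$grid` or
#'   [aggregate_damage()]).
#' @param q3_value The quartile break to exceed.
#' @param model `"A"` or `"B"` stamp for the call records.
#' @return Call tibble (`method = "aggregated"`, basis `cell_quartile` or
#'   `no_data`) with the facility's `cell_id` and cell `proportion`.
#' @export
facility_cell_calls <- function(facilities, grid, q3_value, model) {
  cell <- assign_cells(facilities$x, facilities$y, grid)
  idx <- match(cell, grid$cell_id)
  prop <- grid$proportion[idx]
  empty <- is.na(prop)
  tibble::tibble(
    facility_id = facilities$facility_id, model = model,
    method = "aggregated",
    damaged = !empty & prop > q3_value,
    basis = ifelse(empty, "no_data", "cell_quartile"),
    distance_m = NA_real_,
    cell_id = cell, proportion = prop)
}
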