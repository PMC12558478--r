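#' Decision thresholds for the damage pipeline
#'
#' Bundles every cutoff used downstream. The defaults are the operational
#' values used throughout: a building is "damaged" when more than 40% of its
#' footprint is estimated damaged (strict), a facility within (strictly) 25 m
#' of a damaged building centroid is rescued into the damaged set, spatial
#' aggregation uses 0.125 km^2 cells, and a facility is "likely damaged" when
#' its cell's damaged proportion strictly exceeds the third quartile.
#'
#' @param polygon_damage_cut Damaged-fraction cut for the polygon dialect,
#'   in (0,1); strict greater-than. Default 0.40.
#' @param rescue_radius_m Rescue radius in meters; strict less-than.
#'   Default 25.
#' @param cell_area_km2 Area of each aggregation cell in km^2. Default 0.125.
#' @param quartile_cut Which quartile a cell must strictly exceed for its
#'   facilities to be called damaged: `"Q1"`, `"Q2"` or `"Q3"`. Default
#'   `"Q3"`.
#' @param alpha Two-sided type-I level for all confidence intervals.
#'   Default 0.05.
#' @param centroid_radius_m Matching radius for the centroid dialect
#'   (facility to nearest building centroid). Defaults to `rescue_radius_m`.
#' @param quantile_type Quantile estimator passed to [stats::quantile()]
#'   for the cell-proportion quartiles. Default 7 (linear interpolation
#'   between order statistics).
#' @return A list of class `damage_thresholds`.
#' @examples
#' thresholds()
#' thresholds(polygon_damage_cut = 0.5)
#' @export
thresholds <- function(polygon_damage_cut = 0.40,
                       rescue_radius_m = 25,
                       cell_area_km2 = 0.125,
                       quartile_cut = "Q3",
                       alpha = 0.05,
                       centroid_radius_m = rescue_radius_m,
                       quantile_type = 7) {
  stopifnot(
    is.numeric(polygon_damage_cut), polygon_damage_cut > 0, polygon_damage_cut < 1,
    rescue_radius_m > 0, centroid_radius_m > 0, cell_area_km2 > 0,
    quartile_cut %in% c("Q1", "Q2", "Q3"),
    alpha > 0, alpha < 1
  )
  structure(
    list(polygon_damage_cut = polygon_damage_cut,
         rescue_radius_m = rescue_radius_m,
         cell_area_km2 = cell_area_km2,
         quartile_cut = quartile_cut,
         alpha = alpha,
         centroid_radius_m = centroid_radius_m,
         quantile_type = quantile_type),
    class = "damage_thresholds")
}

#' Error-mode parameters for the synthetic city generator
#'
#' Each parameter switches on one documented failure mode of building-level
#' remote-sensing damage models. Defaults reflect the error frequencies
#' observed in imagery review of the motivating 2023 Türkiye earthquake
#' assessment (merged polygons in ~26% of reviewed facilities, multiple
#' centroids on one building in ~16%, completely destroyed buildings missed
#' in ~12%, facility points geocoded just outside their building in ~6%).
#'
#' @param p_merge Probability that an adjacent dense-zone building pair is
#'   emitted as a single merged polygon whose damaged fraction is the
#'   area-weighted mean of the pair.
#' @param p_multi_centroid Probability that a large building is emitted as
#'   k > 1 centroids (k uniform on \{2, 3\}), one per equal-width wing, each
#'   classified from its wing's damage sub-fraction.
#' @param p_destroyed_miss Probability that a destroyed building is emitted
#'   as (near) undamaged: the polygon dialect draws its fraction uniformly
#'   from \[0, 0.2\]; the centroid dialect emits class 0.
#' @param geocode_sigma_m Isotropic Gaussian jitter (meters) applied to
#'   facility points around their host-building centroid.
#' @param p_geocode_outside Probability that a facility point is displaced
#'   1–5 m outside its host footprint boundary.
#' @return A list of class `error_params`.
#' @examples
#' error_params()                      # study-like error rates
#' error_params(p_merge = 0, p_multi_centroid = 0, p_destroyed_miss = 0,
#'              geocode_sigma_m = 0, p_geocode_outside = 0)  # error-free
#' @export
error_params <- function(p_merge = 0.26,
                         p_multi_centroid = 0.16,
                         p_destroyed_miss = 0.12,
                         geocode_sigma_m = 3,
                         p_geocode_outside = 0.06) {
  p <- c(p_merge, p_multi_centroid, p_destroyed_miss, p_geocode_outside)
  stopifnot(all(p >= 0), all(p <= 1), geocode_sigma_m >= 0)
  structure(
    list(p_merge = p_merge,
         p_multi_centroid = p_multi_centroid,
         p_destroyed_miss = p_destroyed_miss,
         geocode_sigma_m = geocode_sigma_m,
         p_geocode_outside = p_geocode_outside),
    class = "error_params")
}

#' All-zero error parameters
#'
#' Convenience constructor for the error-free generator configuration.
#' @return An [error_params()] object with every error mode switched off.
#' @export
no_errors <- function() {
  error_params(p_merge = 0, p_multi_centroid = 0, p_destroyed_miss = 0,
               geocode_sigma_m = 0, p_geocode_outside = 0)
}
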