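# Independent oracles used across the suite.

# Exact Clopper-Pearson endpoints by bisection on the binomial tails,
# independent of qbeta.
cp_bisect <- function(k, n, alpha = 0.05, tol = 1e-9) {
  upper_tail <- function(p) sum(stats::dbinom(k:n, n, p))   # P(X >= k)
  lower_tail <- function(p) sum(stats::dbinom(0:k, n, p))   # P(X <= k)
  bisect <- function(f, target, increasing) {
    lo <- 0; hi <- 1
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      above <- f(mid) > target
      if (above == increasing) hi <- mid else lo <- mid
      if (hi - lo < tol) break
    }
    (lo + hi) / 2
  }
  low <- if (k == 0) 0 else bisect(upper_tail, alpha / 2, increasing = TRUE)
  high <- if (k == n) 1 else bisect(lower_tail, alpha / 2, increasing = FALSE)
  c(low = low, high = high)
}

# Brute-force overlay for the polygon dialect: literal rule application,
# no shortcuts shared with the implementation's candidate filtering.
brute_overlay_a <- function(facilities, polygons, th) {
  dmg <- polygons$damage_fraction > th$polygon_damage_cut
  vapply(seq_len(nrow(facilities)), function(i) {
    px <- facilities$x[i]; py <- facilities$y[i]
    inter <- FALSE
    for (k in which(dmg)) {
      if (point_in_poly(px, py, polygons$geometry[[k]])) inter <- TRUE
    }
    rescue <- FALSE
    for (k in which(dmg)) {
      cc <- poly_centroid(polygons$geometry[[k]])
      if (sqrt((cc[1] - px)^2 + (cc[2] - py)^2) < th$rescue_radius_m) {
        rescue <- TRUE
      }
    }
    inter || rescue
  }, logical(1))
}

brute_overlay_b <- function(facilities, centroids, th) {
  vapply(seq_len(nrow(facilities)), function(i) {
    d <- sqrt((centroids$x - facilities$x[i])^2 +
              (centroids$y - facilities$y[i])^2)
    ord <- order(d, centroids$building_id)
    k <- ord[1]
    d[k] < th$centroid_radius_m && centroids$damage_class[k] == 1
  }, logical(1))
}

# Brute-force point-to-hexagon assignment: nearest centre over ALL cells.
brute_assign_cells <- function(x, y, grid) {
  vapply(seq_along(x), function(i) {
    d <- (grid$cx - x[i])^2 + (grid$cy - y[i])^2
    grid$cell_id[order(d, grid$cell_id)[1]]
  }, integer(1))
}

# Brute-force duplicate removal: full pairwise union-find.
brute_dedup <- function(facilities, radius_m) {
  n <- nrow(facilities)
  key <- facdamage::normalize_name(facilities$name)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(max(n - 1, 0))) for (j in (i + 1):n) {
    d <- sqrt((facilities$x[i] - facilities$x[j])^2 +
              (facilities$y[i] - facilities$y[j])^2)
    if (key[i] == key[j] && d < radius_m) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  root <- vapply(seq_len(n), find, 0L)
  facilities$facility_id[root == seq_len(n)]
}

# hand kappa from a 2x2 joint table (a = both+, b = A+B-, c = A-B+, d = both-)
hand_kappa <- function(a, b, c, d) {
  n <- a + b + c + d
  po <- (a + d) / n
  pe <- ((a + b) / n) * ((a + c) / n) + ((c + d) / n) * ((b + d) / n)
  (po - pe) / (1 - pe)
}

# small deterministic facility tibble in metric coordinates
make_fac <- function(x, y, ftype = "pharmacy", city = "TestCity",
                     gold = NA_integer_) {
  tibble::tibble(
    facility_id = sprintf("f%03d", seq_along(x)),
    name = sprintf("Facility %d", seq_along(x)),
    ftype = rep_len(ftype, length(x)), city = rep_len(city, length(x)),
    x = x, y = y, gold_label = rep_len(gold, length(x)))
}

# polygon tibble from a list of rings + fractions
make_polys <- function(rings, fractions) {
  tibble::tibble(
    building_id = sprintf("b%03d", seq_along(rings)),
    geometry = lapply(rings, function(r) if (is.matrix(r)) list(r) else r),
    damage_fraction = fractions)
}

shapely_available <- function() {
  isTRUE(tryCatch(
    system2("python", c("-c", shQuote("import shapely")), stdout = FALSE,
            stderr = FALSE) == 0,
    error = function(e) FALSE))
}

# area of the valid-made polygon via shapely, as an external geometry oracle
shapely_valid_area <- function(ring) {
  pts <- paste(sprintf("(%g,%g)", ring[, 1], ring[, 2]), collapse = ",")
  out <- system2("python", c("-c", shQuote(paste0(
    "from shapely.geometry import Polygon\n",
    "from shapely.validation import make_valid\n",
    "print(make_valid(Polygon([", pts, "])).area)"))), stdout = TRUE)
  as.numeric(out[length(out)])
}
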