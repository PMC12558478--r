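# Planar geometry primitives for simple polygons.
#
# Geometries are lists of rings; each ring is an n x 2 numeric matrix of
# vertices (closed or open — helpers close them). The first ring is the
# exterior, any further rings are holes. All coordinates are planar meters.

#' Close a polygon ring
#'
#' Ensures the last vertex repeats the first.
#'
#' @param ring An n x 2 numeric matrix of vertices.
#' @return The ring with first vertex appended if it was open.
#' @keywords internal
ring_close <- function(ring) {
  ring <- as.matrix(ring)
  if (!isTRUE(all(ring[1L, ] == ring[nrow(ring), ]))) {
    ring <- rbind(ring, ring[1L, , drop = FALSE])
  }
  ring
}

# drop the duplicated closing vertex
ring_open <- function(ring) {
  ring <- as.matrix(ring)
  if (nrow(ring) > 1L && all(ring[1L, ] == ring[nrow(ring), ])) {
    ring <- ring[-nrow(ring), , drop = FALSE]
  }
  ring
}

#' Signed area of a ring (shoelace formula)
#'
#' Positive for counter-clockwise vertex order.
#'
#' @param ring An n x 2 numeric matrix.
#' @return Signed area in squared coordinate units.
#' @keywords internal
ring_signed_area <- function(ring) {
  ring <- ring_open(ring)
  n <- nrow(ring)
  if (n < 3L) return(0)
  x <- ring[, 1L]; y <- ring[, 2L]
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

#' Area of a polygon geometry
#'
#' Exterior ring area minus hole areas; orientation-insensitive.
#'
#' @param geom A list of rings (first exterior, rest holes).
#' @return Non-negative area.
#' @export
poly_area <- function(geom) {
  if (is.matrix(geom)) geom <- list(geom)
  a <- abs(ring_signed_area(geom[[1L]]))
  if (length(geom) > 1L) {
    a <- a - sum(vapply(geom[-1L], function(r) abs(ring_signed_area(r)), 0))
  }
  max(a, 0)
}

#' Centroid of a polygon geometry
#'
#' Area-weighted centroid; degenerate (zero-area) rings fall back to the
#' vertex mean.
#'
#' @param geom A list of rings or a single ring matrix.
#' @return Length-2 numeric vector (x, y).
#' @export
poly_centroid <- function(geom) {
  if (is.matrix(geom)) geom <- list(geom)
  cx <- 0; cy <- 0; atot <- 0
  for (k in seq_along(geom)) {
    ring <- ring_open(geom[[k]])
    n <- nrow(ring)
    if (n < 3L) next
    x <- ring[, 1L]; y <- ring[, 2L]
    j <- c(2:n, 1L)
    cross <- x * y[j] - x[j] * y
    a <- sum(cross) / 2
    if (a == 0) next
    sgn <- if (k == 1L) 1 else -1
    cx <- cx + sgn * sum((x + x[j]) * cross) / 6
    cy <- cy + sgn * sum((y + y[j]) * cross) / 6
    atot <- atot + sgn * a
  }
  if (atot == 0) {
    ring <- ring_open(geom[[1L]])
    return(c(mean(ring[, 1L]), mean(ring[, 2L])))
  }
  c(cx / atot, cy / atot)
}

#' Point-in-polygon test
#'
#' Even-odd ray casting against all rings, so holes are excluded. Points on
#' a ring edge count as inside.
#'
#' @param px,py Numeric vectors of point coordinates.
#' @param geom A list of rings or a single ring matrix.
#' @return Logical vector, one element per point.
#' @export
point_in_poly <- function(px, py, geom) {
  if (is.matrix(geom)) geom <- list(geom)
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  for (ring in geom) {
    ring <- ring_open(ring)
    n <- nrow(ring)
    if (n < 3L) next
    x <- ring[, 1L]; y <- ring[, 2L]
    j <- c(n, seq_len(n - 1L))
    for (e in seq_len(n)) {
      x1 <- x[j[e]]; y1 <- y[j[e]]; x2 <- x[e]; y2 <- y[e]
      # boundary test: point collinear with and within the edge's bbox
      d <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
      onb <- abs(d) < 1e-9 * (abs(x2 - x1) + abs(y2 - y1) + 1) &
        px >= pmin(x1, x2) - 1e-12 & px <= pmax(x1, x2) + 1e-12 &
        py >= pmin(y1, y2) - 1e-12 & py <= pmax(y1, y2) + 1e-12
      on_edge <- on_edge | onb
      crosses <- ((y1 > py) != (y2 > py)) &
        (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
      inside <- xor(inside, crosses)
    }
  }
  inside | on_edge
}

# Proper intersection point of segments p1-p2 and p3-p4, or NULL.
# Shared endpoints and collinear overlap do not count.
seg_intersection <- function(p1, p2, p3, p4) {
  d1 <- p2 - p1; d2 <- p4 - p3
  denom <- d1[1L] * d2[2L] - d1[2L] * d2[1L]
  if (abs(denom) < 1e-14) return(NULL)
  t <- ((p3[1L] - p1[1L]) * d2[2L] - (p3[2L] - p1[2L]) * d2[1L]) / denom
  u <- ((p3[1L] - p1[1L]) * d1[2L] - (p3[2L] - p1[2L]) * d1[1L]) / denom
  eps <- 1e-12
  if (t <= eps || t >= 1 - eps || u <= eps || u >= 1 - eps) return(NULL)
  p1 + t * d1
}

#' Test whether a ring is simple (no self-intersection)
#'
#' @param ring An n x 2 matrix.
#' @return TRUE when no pair of non-adjacent edges crosses.
#' @keywords internal
ring_is_simple <- function(ring) {
  is.null(first_self_intersection(ring))
}

# first crossing between non-adjacent edges: list(i, j, pt) or NULL
first_self_intersection <- function(ring) {
  ring <- ring_open(ring)
  n <- nrow(ring)
  if (n < 4L) return(NULL)
  nxt <- c(2:n, 1L)
  for (i in seq_len(n - 2L)) {
    for (jj in (i + 2L):n) {
      if (i == 1L && jj == n) next  # adjacent through the closure
      pt <- seg_intersection(ring[i, ], ring[nxt[i], ], ring[jj, ], ring[nxt[jj], ])
      if (!is.null(pt)) return(list(i = i, j = jj, pt = pt))
    }
  }
  NULL
}

#' Repair a self-intersecting ring
#'
#' Splits the ring at each self-crossing into simple loops (the planar
#' equivalent of a zero-width buffer): a bow-tie becomes its two lobes.
#' Zero-area fragments are dropped.
#'
#' @param ring An n x 2 matrix, possibly self-intersecting.
#' @return A list of simple rings (possibly empty when irreparable).
#' @export
ring_repair <- function(ring, .depth = 0L) {
  ring <- ring_open(ring)
  if (.depth > 16L) return(list())
  hit <- first_self_intersection(ring)
  if (is.null(hit)) {
    if (abs(ring_signed_area(ring)) <= 0) return(list())
    return(list(ring_close(ring)))
  }
  n <- nrow(ring)
  i <- hit$i; j <- hit$j; pt <- hit$pt
  # loop 1: pt, v[i+1..j], back to pt ; loop 2: the complement
  loop1 <- rbind(pt, ring[(i + 1L):j, , drop = FALSE])
  idx2 <- if (j == n) seq_len(i) else c((j + 1L):n, seq_len(i))
  loop2 <- rbind(pt, ring[idx2, , drop = FALSE])
  c(ring_repair(loop1, .depth + 1L), ring_repair(loop2, .depth + 1L))
}

# axis-aligned bounding box of a geometry: c(xmin, ymin, xmax, ymax)
geom_bbox <- function(geom) {
  if (is.matrix(geom)) geom <- list(geom)
  xs <- unlist(lapply(geom, function(r) r[, 1L]))
  ys <- unlist(lapply(geom, function(r) r[, 2L]))
  c(min(xs), min(ys), max(xs), max(ys))
}

# closed rectangle ring from center/width/height
rect_ring <- function(cx, cy, w, h) {
  x1 <- cx - w / 2; x2 <- cx + w / 2
  y1 <- cy - h / 2; y2 <- cy + h / 2
  matrix(c(x1, y1, x2, y1, x2, y2, x1, y2, x1, y1), ncol = 2, byrow = TRUE)
}

# do two axis-aligned rects (c(cx,cy,w,h)) overlap (strictly)?
rects_overlap <- function(a, b) {
  abs(a[1L] - b[1L]) < (a[3L] + b[3L]) / 2 &&
    abs(a[2L] - b[2L]) < (a[4L] + b[4L]) / 2
}

# smallest gap between two axis-aligned rects (0 if touching/overlapping)
rect_gap <- function(a, b) {
  dx <- max(abs(a[1L] - b[1L]) - (a[3L] + b[3L]) / 2, 0)
  dy <- max(abs(a[2L] - b[2L]) - (a[4L] + b[4L]) / 2, 0)
  sqrt(dx^2 + dy^2)
}
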