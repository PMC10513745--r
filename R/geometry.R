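# Planar geometry primitives for an equal-area frame (coordinates in metres).
#
# Geometries are lists of polygons; each polygon is a list of rings (first ring
# outer, any further rings holes); each ring is an open n x 2 matrix (the
# closing vertex is implicit). Overlay routines that need an exact
# intersection clip against *convex* rings (Sutherland-Hodgman), which covers
# every clip window the package uses: grid cells, pixel squares, and the
# convex range/PA polygons the synthetic generator emits.

#' Construct a geometry from rings
#'
#' @param ... One or more polygons, each a list of rings (n x 2 matrices,
#'   outer ring first); or a single ring matrix, taken as one outer ring.
#' @param type `"polygon"`, `"multipolygon"` or `"point"`.
#' @return A `ts_geom` object.
#' @export
ts_geom <- function(..., type = NULL) {
  parts <- list(...)
  if (length(parts) == 1 && is.matrix(parts[[1]])) parts <- list(list(parts[[1]]))
  if (is.null(type)) type <- if (length(parts) > 1) "multipolygon" else "polygon"
  structure(list(type = type, polys = parts), class = "ts_geom")
}

#' Point geometry (used only to exercise point-feature filtering)
#' @param x,y Coordinates in metres.
#' @export
ts_point <- function(x, y) {
  structure(list(type = "point", coords = c(x, y)), class = "ts_geom")
}

is_polygonal <- function(g) g$type %in% c("polygon", "multipolygon")

ring_area_signed <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  sum(x * y2 - x2 * y) / 2
}

#' Polygon area (m^2), holes subtracted
#' @param g A polygonal `ts_geom`.
#' @export
geom_area <- function(g) {
  stopifnot(is_polygonal(g))
  sum(vapply(g$polys, function(poly) {
    a <- abs(ring_area_signed(poly[[1]]))
    if (length(poly) > 1)
      a <- a - sum(vapply(poly[-1], function(h) abs(ring_area_signed(h)), 0))
    a
  }, 0))
}

#' @keywords internal
geom_bbox <- function(g) {
  pts <- do.call(rbind, unlist(g$polys, recursive = FALSE))
  c(xmin = min(pts[, 1]), ymin = min(pts[, 2]),
    xmax = max(pts[, 1]), ymax = max(pts[, 2]))
}

# Even-odd point-in-ring test, vectorized over points.
point_in_ring <- function(px, py, ring) {
  n <- nrow(ring)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Which points fall inside a polygonal geometry
#'
#' Even-odd rule: inside the outer ring and outside every hole, in any part.
#' @param px,py Point coordinates (equal-length vectors).
#' @param g A polygonal `ts_geom`.
#' @return Logical vector.
#' @export
points_in_geom <- function(px, py, g) {
  stopifnot(is_polygonal(g))
  out <- logical(length(px))
  for (poly in g$polys) {
    inp <- point_in_ring(px, py, poly[[1]])
    if (length(poly) > 1)
      for (h in poly[-1]) inp <- inp & !point_in_ring(px, py, h)
    out <- out | inp
  }
  out
}

# Sutherland-Hodgman: clip `subject` (any simple ring) against convex `clip`.
# Returns the clipped ring (possibly 0-row matrix).
clip_ring_convex <- function(subject, clip) {
  if (ring_area_signed(clip) < 0) clip <- clip[rev(seq_len(nrow(clip))), , drop = FALSE]
  out <- subject
  nc <- nrow(clip)
  for (e in seq_len(nc)) {
    if (nrow(out) == 0) break
    a <- clip[e, ]; b <- clip[if (e == nc) 1 else e + 1, ]
    ex <- b[1] - a[1]; ey <- b[2] - a[2]
    inp <- out
    n <- nrow(inp)
    side <- ex * (inp[, 2] - a[2]) - ey * (inp[, 1] - a[1])  # >=0 is inside (left)
    keep <- side >= 0
    res <- matrix(0, 0, 2)
    for (i in seq_len(n)) {
      j <- if (i == n) 1 else i + 1
      p <- inp[i, ]; q <- inp[j, ]
      if (keep[i]) res <- rbind(res, p)
      if (keep[i] != keep[j]) {
        t <- side[i] / (side[i] - side[j])
        res <- rbind(res, p + t * (q - p))
      }
    }
    out <- res
  }
  out
}

#' Intersection area between a geometry and a convex ring
#'
#' Exact for any simple polygonal geometry clipped by a convex window
#' (Sutherland-Hodgman). Holes are clipped and subtracted.
#'
#' @param g A polygonal `ts_geom`.
#' @param clip_ring Convex ring (n x 2 matrix).
#' @return Area in m^2.
#' @export
geom_clip_area <- function(g, clip_ring) {
  stopifnot(is_polygonal(g))
  bb <- geom_bbox(g)
  cb <- c(min(clip_ring[, 1]), min(clip_ring[, 2]),
          max(clip_ring[, 1]), max(clip_ring[, 2]))
  if (cb[1] > bb["xmax"] || cb[3] < bb["xmin"] ||
      cb[2] > bb["ymax"] || cb[4] < bb["ymin"]) return(0)
  sum(vapply(g$polys, function(poly) {
    a <- abs(ring_area_signed2(clip_ring_convex(poly[[1]], clip_ring)))
    if (length(poly) > 1)
      a <- a - sum(vapply(poly[-1], function(h)
        abs(ring_area_signed2(clip_ring_convex(h, clip_ring))), 0))
    a
  }, 0))
}

ring_area_signed2 <- function(ring) if (nrow(ring) < 3) 0 else ring_area_signed(ring)

#' Do two geometries overlap with positive area?
#'
#' One of the two geometries must have convex parts (every outer ring convex,
#' no holes); its parts are used as clip windows against the other geometry.
#'
#' @param g Any polygonal `ts_geom`.
#' @param convex_g A polygonal `ts_geom` with convex, hole-free parts.
#' @param eps Area below which an intersection counts as empty (m^2).
#' @export
geoms_overlap <- function(g, convex_g, eps = 1e-6) {
  overlap_area(g, convex_g) > eps
}

#' @rdname geoms_overlap
#' @export
overlap_area <- function(g, convex_g) {
  stopifnot(is_polygonal(g), is_polygonal(convex_g))
  sum(vapply(convex_g$polys, function(poly) geom_clip_area(g, poly[[1]]), 0))
}

#' Axis-aligned rectangle ring
#' @param xmin,ymin,xmax,ymax Rectangle bounds (metres).
#' @export
rect_ring <- function(xmin, ymin, xmax, ymax) {
  cbind(c(xmin, xmax, xmax, xmin), c(ymin, ymin, ymax, ymax))
}

#' Regular-polygon approximation of an ellipse
#'
#' @param cx,cy Center. @param rx,ry Semi-axes (metres).
#' @param angle Rotation (radians). @param n Vertex count.
#' @return A convex ring matrix.
#' @export
ellipse_ring <- function(cx, cy, rx, ry, angle = 0, n = 48) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  x <- rx * cos(t); y <- ry * sin(t)
  cbind(cx + x * cos(angle) - y * sin(angle),
        cy + x * sin(angle) + y * cos(angle))
}
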