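#' Georeferenced raster grid
#'
#' A minimal in-memory raster: a numeric matrix plus an affine transform in a
#' planar equal-area frame (coordinates in metres). The raster origin is the
#' top-left corner; pixel indices are 0-based row-major in the transform
#' convention, so cell `(i, j)` covers the half-open square
#' `[x0 + j*w, x0 + (j+1)*w) x (y0 - (i+1)*h, y0 - i*h]`.
#'
#' @param values Numeric matrix (rows = north-to-south scanlines).
#' @param x0,y0 World coordinates of the top-left corner (metres).
#' @param px,py Pixel width and height in metres (both positive; `py` is the
#'   southward extent of one pixel).
#' @param nodata Sentinel value marking invalid cells, or `NA` for none.
#'   Cells equal to `nodata` are treated as missing throughout the package.
#' @param crs_tag Identifier of the planar equal-area frame the coordinates
#'   live in. Purely a label: rasters with different tags never align.
#' @param integer_values Logical; if `TRUE` the raster carries integer data
#'   (class codes, labels) and round-trips through GeoTIFF as Int32.
#'
#' @return An object of class `ts_raster`.
#' @export
ts_raster <- function(values, x0 = 0, y0 = NULL, px = 30, py = px,
                      nodata = NA, crs_tag = "local-equal-area",
                      integer_values = is.integer(values)) {
  values <- as.matrix(values)
  stopifnot(nrow(values) >= 1, ncol(values) >= 1, px > 0, py > 0)
  if (is.null(y0)) y0 <- nrow(values) * py
  storage.mode(values) <- if (integer_values) "integer" else "double"
  structure(
    list(values = values,
         transform = c(x0 = x0, y0 = y0, px = px, py = py),
         nodata = nodata, crs_tag = crs_tag,
         integer_values = integer_values),
    class = "ts_raster")
}

#' @export
print.ts_raster <- function(x, ...) {
  tr <- x$transform
  cat(sprintf("<ts_raster> %d x %d, pixel %g x %g m, origin (%g, %g), %s\n",
              nrow(x$values), ncol(x$values), tr["px"], tr["py"],
              tr["x0"], tr["y0"], x$crs_tag))
  v <- raster_values_masked(x)
  cat(sprintf("  values: [%s, %s], nodata cells: %d\n",
              format(suppressWarnings(min(v, na.rm = TRUE))),
              format(suppressWarnings(max(v, na.rm = TRUE))),
              sum(is.na(v))))
  invisible(x)
}

#' @export
dim.ts_raster <- function(x) dim(x$values)

#' Raster values with the nodata sentinel replaced by NA
#' @param r A [ts_raster].
#' @return Numeric matrix with `NA` at masked cells.
#' @export
raster_values_masked <- function(r) {
  v <- r$values
  if (!is.na(r$nodata)) v[v == r$nodata] <- NA
  v
}

#' Per-pixel area in square kilometres
#' @param r A [ts_raster].
#' @export
pixel_area_km2 <- function(r) {
  unname(r$transform["px"] * r$transform["py"] / 1e6)
}

#' World coordinates of pixel centers
#'
#' @param r A [ts_raster].
#' @param rows,cols 1-based row/column indices (defaults: all).
#' @return For vector input of equal length, a two-column matrix `(x, y)`.
#' @export
pixel_centers <- function(r, rows = NULL, cols = NULL) {
  tr <- r$transform
  if (is.null(rows)) {
    rows <- rep(seq_len(nrow(r$values)), times = ncol(r$values))
    cols <- rep(seq_len(ncol(r$values)), each = nrow(r$values))
  }
  cbind(x = tr["x0"] + (cols - 0.5) * tr["px"],
        y = tr["y0"] - (rows - 0.5) * tr["py"],
        deparse.level = 0)
}

#' Test that two rasters share a grid
#'
#' Predicate used before every cross-raster operation: `TRUE` iff both rasters
#' have the same shape, the same affine transform (within `tol`), and the same
#' `crs_tag`. Misalignment is never repaired by resampling.
#'
#' @param a,b Rasters.
#' @param tol Absolute tolerance on the transform coefficients (metres).
#' @return Logical scalar.
#' @export
assert_aligned <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$transform - b$transform) < tol) &&
    identical(a$crs_tag, b$crs_tag)
}

check_aligned <- function(a, b, what = "rasters") {
  if (!assert_aligned(a, b))
    stop(sprintf("%s are not grid-aligned (shape/transform/crs must match)", what))
  invisible(TRUE)
}
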