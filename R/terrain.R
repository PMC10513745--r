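# Terrain stratification: slope from the DEM, then lowland/hill/mountain
# classes from joint elevation-slope bands.

#' Slope in degrees from a DEM (Horn's method)
#'
#' Horn's 3x3 finite-difference operator on the metre-scaled grid, the
#' standard GIS slope estimator. Border cells use edge replication; nodata
#' cells propagate (a nodata neighbour is replaced by the centre value, a
#' nodata centre stays nodata).
#'
#' @param dem A [ts_raster] of elevations in metres.
#' @return A float [ts_raster] of slope in degrees, in `[0, 90)`.
#' @export
compute_slope <- function(dem) {
  v <- raster_values_masked(dem)
  nr <- nrow(v); nc <- ncol(v)
  if (nr < 3 || nc < 3) stop("DEM must be at least 3x3 cells")
  px <- dem$transform[["px"]]; py <- dem$transform[["py"]]

  # edge-replicated shift: sh(di, dj) = v[i+di, j+dj]
  sh <- function(di, dj) {
    ri <- pmin(pmax(seq_len(nr) + di, 1), nr)
    cj <- pmin(pmax(seq_len(nc) + dj, 1), nc)
    v[ri, cj, drop = FALSE]
  }
  fill <- function(m) { m[is.na(m)] <- v[is.na(m)]; m }
  a <- fill(sh(-1, -1)); b <- fill(sh(-1, 0)); cc <- fill(sh(-1, 1))
  d <- fill(sh(0, -1));                        f <- fill(sh(0, 1))
  g <- fill(sh(1, -1));  h <- fill(sh(1, 0));  i <- fill(sh(1, 1))

  gx <- ((cc + 2 * f + i) - (a + 2 * d + g)) / (8 * px)
  gy <- ((g + 2 * h + i) - (a + 2 * b + cc)) / (8 * py)
  slope <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
  slope[is.na(v)] <- NA
  r <- ts_raster(slope, x0 = dem$transform[["x0"]], y0 = dem$transform[["y0"]],
                 px = px, py = py, nodata = NA, crs_tag = dem$crs_tag)
  r
}

#' Relief classes used by the package
#' @export
RELIEF_CODES <- c(lowland = 0L, hill = 1L, mountain = 2L)

#' Classify cells into lowland / hill / mountain
#'
#' Joint elevation-slope bands (elevation bands half-open `[lower, upper)`,
#' elevations below 0 m treated with the lowest band's rules):
#' \itemize{
#'   \item elevation < 1,000 m: slope <= 15 deg lowland, > 15 deg hill
#'   \item 1,000-1,200 m: slope <= 8 deg lowland, > 8 deg hill
#'   \item 1,200-1,500 m: slope <= 3 deg hill, > 3 deg mountain
#'   \item >= 1,500 m: mountain
#' }
#' Highland = hill or mountain; lowland = plains and terraces. The bands are
#' exhaustive and mutually exclusive, so every valid cell gets exactly one
#' class.
#'
#' @param dem Elevation [ts_raster] (metres).
#' @param slope Slope [ts_raster] (degrees), grid-aligned with `dem`.
#' @return Integer [ts_raster] with codes in [RELIEF_CODES] (nodata 255).
#' @export
classify_relief <- function(dem, slope) {
  check_aligned(dem, slope, "dem and slope")
  e <- raster_values_masked(dem)
  s <- raster_values_masked(slope)
  e[!is.na(e) & e < 0] <- 0  # below-sea-level land follows the lowest band

  cls <- matrix(NA_integer_, nrow(e), ncol(e))
  low <- e < 1000
  mid <- e >= 1000 & e < 1200
  upp <- e >= 1200 & e < 1500
  top <- e >= 1500
  cls[low & s <= 15] <- RELIEF_CODES[["lowland"]]
  cls[low & s > 15]  <- RELIEF_CODES[["hill"]]
  cls[mid & s <= 8]  <- RELIEF_CODES[["lowland"]]
  cls[mid & s > 8]   <- RELIEF_CODES[["hill"]]
  cls[upp & s <= 3]  <- RELIEF_CODES[["hill"]]
  cls[upp & s > 3]   <- RELIEF_CODES[["mountain"]]
  cls[top]           <- RELIEF_CODES[["mountain"]]
  cls[is.na(e) | is.na(s)] <- NA_integer_
  cls[is.na(cls)] <- 255L
  ts_raster(cls, x0 = dem$transform[["x0"]], y0 = dem$transform[["y0"]],
            px = dem$transform[["px"]], py = dem$transform[["py"]],
            nodata = 255, crs_tag = dem$crs_tag, integer_values = TRUE)
}

#' Binary highland mask from a relief raster
#' @param relief Output of [classify_relief()].
#' @return Integer [ts_raster]: 1 = highland (hill or mountain), 0 = lowland.
#' @export
highland_mask <- function(relief) {
  v <- raster_values_masked(relief)
  m <- matrix(255L, nrow(v), ncol(v))
  m[!is.na(v)] <- as.integer(v[!is.na(v)] >= RELIEF_CODES[["hill"]])
  ts_raster(m, x0 = relief$transform[["x0"]], y0 = relief$transform[["y0"]],
            px = relief$transform[["px"]], py = relief$transform[["py"]],
            nodata = 255, crs_tag = relief$crs_tag, integer_values = TRUE)
}

#' Aggregate the highland mask to an analysis grid
#'
#' A grid cell is called highland when more than half of the valid DEM
#' sub-pixels whose centres fall in the cell are highland.
#'
#' @param relief DEM-resolution relief raster ([classify_relief()]).
#' @param grid A [build_grid()] grid.
#' @return Integer matrix (grid shape): 1 highland, 0 lowland, NA no valid
#'   sub-pixels.
#' @export
grid_highland <- function(relief, grid) {
  hl <- raster_values_masked(highland_mask(relief))
  idx <- cell_index_of_pixels(relief, grid)
  ok <- !is.na(hl) & !is.na(idx)
  tot <- tabulate_cells(idx[ok], grid)
  hi <- tabulate_cells(idx[ok & hl == 1], grid)
  out <- matrix(NA_integer_, grid$nrow, grid$ncol)
  out[tot > 0] <- as.integer(hi[tot > 0] / tot[tot > 0] > 0.5)
  out
}
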