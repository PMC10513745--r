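# The threat-degree index: 1 km analysis grid, density surfaces of patch
# number / patch area / species involvement, min-max normalization, the
# geometric-mean composite, mean/SD level classification, and the
# highland-lowland difference statistic.

#' Build the analysis grid
#'
#' Tessellates the extent with square cells (1 km x 1 km by default),
#' top-left anchored: cell `(i, j)` (0-based) covers
#' `[x0 + j*c, x0 + (j+1)*c) x (y0 - (i+1)*c, y0 - i*c]`. Boundary cells are
#' clipped to the extent, so their areas may be below one cell area.
#'
#' @param extent Named vector/list with `x0`, `y0` (top-left corner, metres),
#'   `width`, `height` (metres); [raster_extent()] builds one from a raster.
#' @param cell_size_km Cell edge in kilometres.
#' @param crs_tag Frame identifier.
#' @return A `ts_grid` object.
#' @export
build_grid <- function(extent, cell_size_km = 1, crs_tag = "local-equal-area") {
  if (cell_size_km <= 0) stop("cell size must be positive")
  cs <- cell_size_km * 1000
  w <- extent[["width"]]; h <- extent[["height"]]
  if (w < cs || h < cs) stop("extent smaller than one grid cell")
  structure(list(x0 = extent[["x0"]], y0 = extent[["y0"]],
                 cell = cs,
                 nrow = as.integer(ceiling(h / cs - 1e-9)),
                 ncol = as.integer(ceiling(w / cs - 1e-9)),
                 width = w, height = h,
                 crs_tag = crs_tag),
            class = "ts_grid")
}

#' @export
print.ts_grid <- function(x, ...) {
  cat(sprintf("<ts_grid> %d x %d cells of %g km, origin (%g, %g)\n",
              x$nrow, x$ncol, x$cell / 1000, x$x0, x$y0))
  invisible(x)
}

#' Extent of a raster
#' @param r A [ts_raster].
#' @return List with `x0`, `y0`, `width`, `height` (metres).
#' @export
raster_extent <- function(r) {
  tr <- r$transform
  list(x0 = tr[["x0"]], y0 = tr[["y0"]],
       width = ncol(r$values) * tr[["px"]],
       height = nrow(r$values) * tr[["py"]])
}

#' Cell areas in km^2 (boundary cells clipped)
#' @param grid A `ts_grid`.
#' @return Numeric matrix of shape `nrow x ncol`.
#' @export
cell_areas_km2 <- function(grid) {
  wj <- pmin(grid$cell, grid$width - (seq_len(grid$ncol) - 1) * grid$cell)
  hi <- pmin(grid$cell, grid$height - (seq_len(grid$nrow) - 1) * grid$cell)
  outer(hi, wj) / 1e6
}

#' Ring of one grid cell
#' @param grid A `ts_grid`. @param i,j 1-based row/column.
#' @export
cell_ring <- function(grid, i, j) {
  rect_ring(grid$x0 + (j - 1) * grid$cell,
            grid$y0 - min(i * grid$cell, grid$height),
            grid$x0 + min(j * grid$cell, grid$width),
            grid$y0 - (i - 1) * grid$cell)
}

#' Cell centres as a matrix of points
#' @param grid A `ts_grid`.
#' @return `(nrow*ncol) x 2` matrix in cell-id order (row-major).
#' @export
cell_centers <- function(grid) {
  i <- rep(seq_len(grid$nrow), each = grid$ncol)
  j <- rep(seq_len(grid$ncol), times = grid$nrow)
  cbind(grid$x0 + (j - 0.5) * grid$cell, grid$y0 - (i - 0.5) * grid$cell)
}

# row-major 1-based cell id of every pixel centre of raster r; NA outside grid
cell_index_of_pixels <- function(r, grid) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  tr <- r$transform
  cxs <- tr[["x0"]] + (seq_len(nc) - 0.5) * tr[["px"]]
  cys <- tr[["y0"]] - (seq_len(nr) - 0.5) * tr[["py"]]
  jj <- floor((cxs - grid$x0) / grid$cell)            # 0-based col per pixel col
  ii <- floor((grid$y0 - cys) / grid$cell)            # 0-based row per pixel row
  jj[jj < 0 | jj >= grid$ncol] <- NA
  ii[ii < 0 | ii >= grid$nrow] <- NA
  outer(ii * grid$ncol, jj + 1, `+`)                  # matrix, row-major ids
}

tabulate_cells <- function(ids, grid) {
  n <- grid$nrow * grid$ncol
  matrix(tabulate(ids, nbins = n), grid$nrow, grid$ncol, byrow = TRUE)
}

grid_raster <- function(grid, values, integer_values = FALSE, nodata = NA) {
  ts_raster(values, x0 = grid$x0, y0 = grid$y0,
            px = grid$cell, py = grid$cell, nodata = nodata,
            crs_tag = grid$crs_tag, integer_values = integer_values)
}

#' Density surfaces of the three threat components
#'
#' Per grid cell: `N` = number of distinct patches with at least one pixel
#' centre in the cell (a patch spanning cells counts in each), `A` = expansion
#' area from pixels whose centres fall in the cell (pixel count x pixel area,
#' so total area is conserved across cells), and `T` = distinct threatened
#' species whose range covers at least one of those pixel centres.
#'
#' @param grid A `ts_grid`.
#' @param patches A `ts_patchset` ([extract_patches()]).
#' @param sp A filtered `ts_species` ([filter_threatened()]), or NULL for T=0.
#' @param valid Optional [ts_raster] grid-aligned with the label raster whose
#'   nodata cells mark pixels excluded from analysis; cells with no valid
#'   pixel centre get NA densities.
#' @return List of three [ts_raster]s `N`, `A`, `T` on the grid.
#' @export
compute_density_surfaces <- function(grid, patches, sp = NULL, valid = NULL) {
  lab <- patches$label_raster
  if (!identical(lab$crs_tag, grid$crs_tag))
    stop("patches and grid are in different frames")
  idx <- cell_index_of_pixels(lab, grid)
  labv <- lab$values
  ones <- which(labv > 0L & !is.na(idx))
  ids <- idx[ones]

  A <- tabulate_cells(ids, grid) * pixel_area_km2(lab)

  pair <- (ids - 1) * (max(labv) + 1) + labv[ones]
  keep <- !duplicated(pair)
  N <- tabulate_cells(ids[keep], grid)

  Tm <- matrix(0L, grid$nrow, grid$ncol)
  if (!is.null(sp) && length(sp) > 0 && length(ones) > 0) {
    nr <- nrow(labv)
    ctr <- pixel_centers(lab, rows = ((ones - 1L) %% nr) + 1L,
                         cols = ((ones - 1L) %/% nr) + 1L)
    for (k in seq_along(sp$binomial)) {
      inside <- points_in_geom(ctr[, 1], ctr[, 2], sp$range[[k]])
      if (any(inside)) {
        hit <- unique(ids[inside])
        Tm[cbind((hit - 1) %/% grid$ncol + 1, (hit - 1) %% grid$ncol + 1)] <-
          Tm[cbind((hit - 1) %/% grid$ncol + 1, (hit - 1) %% grid$ncol + 1)] + 1L
      }
    }
  }

  na_cells <- NULL
  if (!is.null(valid)) {
    check_aligned(lab, valid, "label and validity rasters")
    vv <- raster_values_masked(valid)
    n_valid <- tabulate_cells(idx[!is.na(vv) & !is.na(idx)], grid)
    na_cells <- n_valid == 0
    N[na_cells] <- NA; A[na_cells] <- NA; Tm[na_cells] <- NA
  }
  # counts are non-negative, so -1 is a safe sentinel for no-data cells
  list(N = grid_raster(grid, N, integer_values = TRUE, nodata = -1),
       A = grid_raster(grid, A),
       T = grid_raster(grid, Tm, integer_values = TRUE, nodata = -1))
}

#' Min-max normalize a density surface to percent
#'
#' `(X - Xmin) / (Xmax - Xmin) * 100` over the valid cells, with the extremes
#' taken over the whole surface once (zero-density cells included), so the
#' minimum maps to 0 and the maximum to 100. Invariant under positive
#' rescaling of `X`. A constant surface normalizes to all zeros with a
#' warning.
#'
#' @param X A [ts_raster] density surface.
#' @return A float [ts_raster] in `[0, 100]`.
#' @export
normalize_surface <- function(X) {
  v <- raster_values_masked(X)
  ok <- !is.na(v)
  if (!any(ok)) stop("no valid cells to normalize")
  mn <- min(v[ok]); mx <- max(v[ok])
  out <- matrix(NA_real_, nrow(v), ncol(v))
  if (mx == mn) {
    warning("degenerate surface (max == min): normalized to all zeros")
    out[ok] <- 0
  } else {
    out[ok] <- (v[ok] - mn) / (mx - mn) * 100
  }
  ts_raster(out, x0 = X$transform[["x0"]], y0 = X$transform[["y0"]],
            px = X$transform[["px"]], py = X$transform[["py"]],
            nodata = NA, crs_tag = X$crs_tag)
}

#' Threat degree: geometric mean of the normalized components
#'
#' `TD = (dN * dA * dT)^(1/3)` cellwise, in `[0, 100]` percent. Any zero
#' component forces TD = 0, so expansion-free cells always carry no threat.
#'
#' @param dN,dA,dT Grid-aligned normalized surfaces ([normalize_surface()]).
#' @return A float [ts_raster].
#' @export
threat_degree <- function(dN, dA, dT) {
  check_aligned(dN, dA, "normalized surfaces")
  check_aligned(dN, dT, "normalized surfaces")
  n <- raster_values_masked(dN); a <- raster_values_masked(dA)
  t_ <- raster_values_masked(dT)
  if (any(n < 0 | a < 0 | t_ < 0, na.rm = TRUE))
    stop("normalized surfaces must be non-negative")
  td <- (n * a * t_)^(1 / 3)
  ts_raster(td, x0 = dN$transform[["x0"]], y0 = dN$transform[["y0"]],
            px = dN$transform[["px"]], py = dN$transform[["py"]],
            nodata = NA, crs_tag = dN$crs_tag)
}

#' Level cut-offs from map mean and standard deviation
#'
#' Low below `mean + 0.5 sd`, Moderate from `mean + 0.5 sd` to
#' `mean + 1.5 sd` (closed on both ends), High above.
#'
#' @param mean,sd Mean and standard deviation of the threat-degree map over
#'   its statistic domain.
#' @return Named vector `c(low_cut, high_cut)`.
#' @export
threat_thresholds <- function(mean, sd) {
  c(low_cut = mean + 0.5 * sd, high_cut = mean + 1.5 * sd)
}

#' Recover map mean and standard deviation from published cut-offs
#'
#' Inverts [threat_thresholds()]: given the Low/Moderate and Moderate/High
#' cut-offs of a mean/SD classification, returns the map statistics they
#' encode (`sd = high - low`, `mean = low - 0.5 sd`).
#'
#' @param low_cut,high_cut The two dividing values.
#' @return Named vector `c(mean, sd)`.
#' @export
solve_threshold_stats <- function(low_cut, high_cut) {
  sd <- high_cut - low_cut
  c(mean = low_cut - 0.5 * sd, sd = sd)
}

#' Threat level codes
#' @export
THREAT_LEVELS <- c(none = 0L, low = 1L, moderate = 2L, high = 3L)

#' Classify the threat surface into Low / Moderate / High
#'
#' Statistics (mean, sample SD) are computed over the statistic domain —
#' by default the threatened cells (TD > 0), the domain on which the map's
#' published averages are defined — and the cut-offs follow
#' [threat_thresholds()]. Valid cells outside the domain get level `none`.
#'
#' @param td Threat-degree [ts_raster].
#' @param domain_mask Optional logical matrix selecting the statistic domain;
#'   default `td > 0`.
#' @return List: `levels` (integer [ts_raster], codes in [THREAT_LEVELS],
#'   nodata 255) and `thresholds` (list `mean`, `sd`, `low_cut`, `high_cut`,
#'   `n`).
#' @export
classify_threat <- function(td, domain_mask = NULL) {
  v <- raster_values_masked(td)
  if (is.null(domain_mask)) domain_mask <- !is.na(v) & v > 0
  domain_mask <- domain_mask & !is.na(v)
  if (!any(domain_mask)) stop("empty statistic domain")
  x <- v[domain_mask]
  m <- mean(x); s <- stats::sd(x)
  if (length(x) == 1 || s == 0) {
    warning("zero spread in the statistic domain: all cells classified Low")
    s <- 0
  }
  cuts <- threat_thresholds(m, s)
  levels <- apply_threat_levels(td, cuts[["low_cut"]], cuts[["high_cut"]],
                                domain_mask)
  list(levels = levels,
       thresholds = list(mean = m, sd = s,
                         low_cut = unname(cuts["low_cut"]),
                         high_cut = unname(cuts["high_cut"]),
                         n = length(x)))
}

#' Apply given level cut-offs to a threat surface
#'
#' Classifies cells into Low (`TD < low_cut`), Moderate
#' (`low_cut <= TD <= high_cut`, closed at both ends) and High
#' (`TD > high_cut`). Used by [classify_threat()] with map-derived cut-offs,
#' and directly when imposing one map's thresholds on another (for example
#' continental cut-offs on a national surface).
#'
#' @param td Threat-degree [ts_raster].
#' @param low_cut,high_cut Dividing values.
#' @param domain_mask Logical matrix of cells to classify; valid cells
#'   outside it get level `none`. Default: cells with TD > 0.
#' @return Integer [ts_raster] with codes in [THREAT_LEVELS] (nodata 255).
#' @export
apply_threat_levels <- function(td, low_cut, high_cut, domain_mask = NULL) {
  v <- raster_values_masked(td)
  if (is.null(domain_mask)) domain_mask <- !is.na(v) & v > 0
  domain_mask <- domain_mask & !is.na(v)
  lev <- matrix(255L, nrow(v), ncol(v))
  lev[!is.na(v)] <- THREAT_LEVELS[["none"]]
  lev[domain_mask & v < low_cut] <- THREAT_LEVELS[["low"]]
  lev[domain_mask & v >= low_cut & v <= high_cut] <- THREAT_LEVELS[["moderate"]]
  lev[domain_mask & v > high_cut] <- THREAT_LEVELS[["high"]]
  ts_raster(lev, x0 = td$transform[["x0"]], y0 = td$transform[["y0"]],
            px = td$transform[["px"]], py = td$transform[["py"]],
            nodata = 255, crs_tag = td$crs_tag, integer_values = TRUE)
}

#' Highland-lowland threat difference within a zone
#'
#' `D = mean(TD | highland cells) - mean(TD | lowland cells)`, with means over
#' the statistic domain (threatened cells by default, matching the zonal
#' averages). Returns `NA` when a stratum has no cells in the zone.
#'
#' @param td Threat-degree [ts_raster] on the analysis grid.
#' @param highland Integer/logical matrix from [grid_highland()] (1 highland,
#'   0 lowland, NA unknown), grid shape.
#' @param zone Optional polygonal [ts_geom]; default whole grid.
#' @param domain Either `"threatened"` (cells with TD > 0) or `"all"`.
#' @return Numeric `D` in percentage points.
#' @export
highland_lowland_difference <- function(td, highland, zone = NULL,
                                        domain = c("threatened", "all")) {
  domain <- match.arg(domain)
  v <- raster_values_masked(td)
  stopifnot(identical(dim(v), dim(highland)))
  sel <- !is.na(v) & !is.na(highland)
  if (domain == "threatened") sel <- sel & v > 0
  if (!is.null(zone)) {
    grid_like <- list(x0 = td$transform[["x0"]], y0 = td$transform[["y0"]],
                      cell = td$transform[["px"]],
                      nrow = nrow(v), ncol = ncol(v),
                      width = ncol(v) * td$transform[["px"]],
                      height = nrow(v) * td$transform[["py"]])
    ctr <- cell_centers(structure(grid_like, class = "ts_grid"))
    inz <- matrix(points_in_geom(ctr[, 1], ctr[, 2], zone),
                  nrow(v), ncol(v), byrow = TRUE)
    sel <- sel & inz
  }
  hi <- sel & highland == 1
  lo <- sel & highland == 0
  if (!any(hi) || !any(lo)) return(NA_real_)
  mean(v[hi]) - mean(v[lo])
}
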