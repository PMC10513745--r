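# Zonal aggregation of the threat surface: per-zone means by relief stratum,
# per-level areas and proportions, and the protected-area filter.

#' Filter a protected-area layer to analysable records
#'
#' Keeps polygon features whose establishment (status) year is available and
#' earlier than `cutoff_year`; point features and records without a year are
#' dropped. Retained polygons that overlap (or share a name) are dissolved
#' into one merged feature, so overlapping designations are never
#' double-counted; the merged area counts overlap once (computed on a fine
#' point grid over the group's bounding box).
#'
#' @param pa_layer A [ts_vector] with attributes `name` and `status_year`.
#' @param cutoff_year Exclusive upper bound on status year (default 2000,
#'   i.e. only PAs established before 2000 are kept).
#' @param area_grid_n Number of subdivisions per axis for merged-area
#'   estimation.
#' @param quiet Suppress the summary message.
#' @return A [ts_vector] of merged features with attributes `name`,
#'   `n_members`, `area_km2`; the layer also carries `total_area_km2`.
#' @export
filter_pas <- function(pa_layer, cutoff_year = 2000, area_grid_n = 400,
                       quiet = FALSE) {
  stopifnot(inherits(pa_layer, "ts_vector"))
  years <- suppressWarnings(as.numeric(feature_attr(pa_layer, "status_year")))
  polygonal <- vapply(pa_layer$features, function(f) is_polygonal(f$geometry), TRUE)
  keep <- polygonal & !is.na(years) & years < cutoff_year
  n_pts <- sum(!polygonal); n_noyr <- sum(polygonal & is.na(years))
  kept <- pa_layer$features[keep]
  if (length(kept) == 0) {
    if (!quiet) message("no protected areas retained")
    out <- ts_vector(list(), crs_tag = pa_layer$crs_tag)
    out$total_area_km2 <- 0
    return(out)
  }
  names_ <- vapply(kept, function(f) f$attributes$name %||% NA_character_, "")

  # merge groups: same non-missing name, or spatial overlap (convex parts)
  n <- length(kept)
  adj <- integer(0)
  if (n > 1) {
    bbs <- lapply(kept, function(f) geom_bbox(f$geometry))
    for (a in seq_len(n - 1)) for (b in (a + 1):n) {
      same_name <- !is.na(names_[a]) && !is.na(names_[b]) && names_[a] == names_[b]
      bb_touch <- !(bbs[[a]]["xmax"] < bbs[[b]]["xmin"] ||
                    bbs[[b]]["xmax"] < bbs[[a]]["xmin"] ||
                    bbs[[a]]["ymax"] < bbs[[b]]["ymin"] ||
                    bbs[[b]]["ymax"] < bbs[[a]]["ymin"])
      if (same_name ||
          (bb_touch && geoms_overlap(kept[[a]]$geometry, kept[[b]]$geometry)))
        adj <- c(adj, a, b)
    }
  }
  g <- igraph::make_graph(edges = adj, n = n, directed = FALSE)
  memb <- igraph::components(g)$membership

  merged <- lapply(seq_len(max(memb)), function(gid) {
    members <- kept[memb == gid]
    polys <- unlist(lapply(members, function(f) f$geometry$polys),
                    recursive = FALSE)
    geom <- structure(list(type = if (length(polys) > 1) "multipolygon"
                                  else "polygon", polys = polys),
                      class = "ts_geom")
    area <- if (length(members) == 1) geom_area(members[[1]]$geometry) / 1e6
            else merged_area_km2(geom, area_grid_n)
    nm <- names_[memb == gid]
    list(geometry = geom,
         attributes = list(name = if (all(is.na(nm))) sprintf("merged_%d", gid)
                                  else nm[!is.na(nm)][1],
                           n_members = length(members),
                           area_km2 = area))
  })
  total <- sum(vapply(merged, function(f) f$attributes$area_km2, 0))
  if (!quiet)
    message(sprintf(
      "protected areas: %d features -> kept %d (dropped %d points, %d missing year, %d post-cutoff) -> %d merged, %.2f km2",
      length(pa_layer$features), n, n_pts, n_noyr,
      sum(polygonal & !is.na(years) & years >= cutoff_year),
      length(merged), total))
  out <- ts_vector(merged, crs_tag = pa_layer$crs_tag)
  out$total_area_km2 <- total
  out
}

# union area of possibly-overlapping parts, by fine point-grid counting
merged_area_km2 <- function(geom, n = 400) {
  bb <- geom_bbox(geom)
  dx <- (bb["xmax"] - bb["xmin"]) / n
  dy <- (bb["ymax"] - bb["ymin"]) / n
  xs <- bb["xmin"] + (seq_len(n) - 0.5) * dx
  ys <- bb["ymin"] + (seq_len(n) - 0.5) * dy
  px <- rep(xs, times = n); py <- rep(ys, each = n)
  unname(sum(points_in_geom(px, py, geom)) * dx * dy / 1e6)
}

#' Per-zone summary of the threat surface
#'
#' For each zone: mean TD over threatened cells (overall and by relief
#' stratum), the highland-lowland difference `D`, per-level areas and their
#' proportions of the threatened area, the threatened area itself and its
#' share of the zone. Cell-to-zone membership is by cell centre; a zone
#' containing no cells is reported with `n_cells = 0` and NA statistics.
#'
#' @param td Threat-degree [ts_raster] on the analysis grid.
#' @param levels Level [ts_raster] from [classify_threat()].
#' @param zones A [ts_vector] of zone polygons (attribute `name` used when
#'   present), or NULL for a single whole-extent zone named `"all"`.
#' @param grid The `ts_grid` the surfaces live on.
#' @param highland Matrix from [grid_highland()], or NULL to skip strata.
#' @return A data.frame with one row per zone.
#' @export
zonal_summary <- function(td, levels, zones, grid, highland = NULL) {
  v <- raster_values_masked(td)
  lv <- raster_values_masked(levels)
  areas <- cell_areas_km2(grid)
  ctr <- cell_centers(grid)
  nz <- if (is.null(zones)) 1L else length(zones$features)

  rows <- lapply(seq_len(nz), function(z) {
    if (is.null(zones)) {
      inz <- matrix(TRUE, grid$nrow, grid$ncol)
      nm <- "all"
    } else {
      f <- zones$features[[z]]
      inz <- matrix(points_in_geom(ctr[, 1], ctr[, 2], f$geometry),
                    grid$nrow, grid$ncol, byrow = TRUE)
      nm <- f$attributes$name %||% sprintf("zone_%d", z)
    }
    valid <- inz & !is.na(v)
    thr <- valid & v > 0
    zone_area <- sum(areas[valid])
    thr_area <- sum(areas[thr])
    lvl_area <- vapply(1:3, function(code)
      sum(areas[thr & !is.na(lv) & lv == code]), 0)
    mean_all <- if (any(thr)) mean(v[thr]) else NA_real_
    if (!is.null(highland)) {
      hi <- thr & !is.na(highland) & highland == 1
      lo <- thr & !is.na(highland) & highland == 0
      mean_hi <- if (any(hi)) mean(v[hi]) else NA_real_
      mean_lo <- if (any(lo)) mean(v[lo]) else NA_real_
      D <- if (any(hi) && any(lo)) mean_hi - mean_lo else NA_real_
    } else mean_hi <- mean_lo <- D <- NA_real_
    props <- if (thr_area > 0) lvl_area / thr_area * 100 else rep(NA_real_, 3)
    data.frame(zone = nm, n_cells = sum(valid),
               mean_td = mean_all,
               mean_td_highland = mean_hi, mean_td_lowland = mean_lo,
               D = D,
               area_low_km2 = lvl_area[1], area_moderate_km2 = lvl_area[2],
               area_high_km2 = lvl_area[3],
               prop_low = props[1], prop_moderate = props[2],
               prop_high = props[3],
               threatened_area_km2 = thr_area,
               zone_area_km2 = zone_area,
               threatened_fraction = if (zone_area > 0)
                 thr_area / zone_area * 100 else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Mean threat degree per zone (means part only)
#'
#' Convenience wrapper around [zonal_summary()] returning the per-zone mean
#' TD columns and `D`.
#'
#' @inheritParams zonal_summary
#' @export
zonal_mean_td <- function(td, zones, grid, highland = NULL) {
  lev <- grid_raster(grid, matrix(255L, grid$nrow, grid$ncol),
                     integer_values = TRUE, nodata = 255)
  zonal_summary(td, lev, zones, grid, highland)[
    , c("zone", "n_cells", "mean_td", "mean_td_highland",
        "mean_td_lowland", "D")]
}

#' Per-level areas and proportions per zone (areas part only)
#'
#' @inheritParams zonal_summary
#' @export
level_area_stats <- function(levels, zones, grid, td = NULL) {
  if (is.null(td)) {
    lv <- raster_values_masked(levels)
    tdv <- matrix(0, grid$nrow, grid$ncol)
    tdv[!is.na(lv) & lv >= 1] <- 1
    tdv[is.na(lv)] <- NA
    td <- grid_raster(grid, tdv)
  }
  zonal_summary(td, levels, zones, grid)[
    , c("zone", "area_low_km2", "area_moderate_km2", "area_high_km2",
        "prop_low", "prop_moderate", "prop_high",
        "threatened_area_km2", "zone_area_km2", "threatened_fraction")]
}

#' Proportions of per-level areas
#'
#' Shares (percent) of the threatened area held by each level; the arithmetic
#' behind every per-level proportion the zonal tables report.
#'
#' @param areas Numeric vector of per-level areas (same unit).
#' @return Proportions in percent, summing to 100.
#' @export
level_proportions <- function(areas) {
  tot <- sum(areas)
  if (tot <= 0) return(rep(NA_real_, length(areas)))
  areas / tot * 100
}
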