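# PA filtering/merging and zonal aggregation of the threat surface.

pa_feature <- function(ring_or_point, name, year) {
  g <- if (is.matrix(ring_or_point)) ts_geom(ring_or_point) else ring_or_point
  list(geometry = g, attributes = list(name = name, status_year = year))
}

test_that("the PA filter drops post-cutoff, missing-year and point records", {
  layer <- ts_vector(list(
    pa_feature(rect_ring(0, 0, 1000, 1000), "Old reserve", 1990),
    pa_feature(rect_ring(3000, 0, 4000, 1000), "New park", 2005),
    pa_feature(rect_ring(6000, 0, 7000, 1000), "No year", NA),
    pa_feature(ts_point(500, 500), "Point record", 1980),
    pa_feature(rect_ring(0, 3000, 1000, 4000), "Edge year", 2000)))
  out <- filter_pas(layer, quiet = TRUE)
  expect_equal(length(out), 1L)
  expect_equal(out$features[[1]]$attributes$name, "Old reserve")
  expect_equal(out$total_area_km2, 1)
})

test_that("everything is retained when all PAs are old polygons with years", {
  cfg <- tiny_cfg(n_pas = 10, pa_pre2000_fraction = 1,
                  pa_missing_year_fraction = 0, pa_point_fraction = 0)
  pas <- generate_pas(cfg)
  out <- filter_pas(pas, quiet = TRUE)
  expect_equal(sum(feature_attr(out, "n_members")), 10)
})

test_that("overlapping retained PAs merge and count overlap area once", {
  layer <- ts_vector(list(
    pa_feature(rect_ring(0, 0, 2000, 2000), "A", 1980),
    pa_feature(rect_ring(1000, 0, 3000, 2000), "B", 1990),   # overlaps A
    pa_feature(rect_ring(10000, 0, 11000, 1000), "C", 1970)))
  out <- filter_pas(layer, quiet = TRUE)
  expect_equal(length(out), 2L)
  merged <- out$features[[which(feature_attr(out, "n_members") == 2)]]
  # union of the two 2x2 km squares = 3 km x 2 km = 6 km2 (overlap once)
  expect_equal(merged$attributes$area_km2, 6, tolerance = 0.02)
  expect_equal(out$total_area_km2, 7, tolerance = 0.02)
})

test_that("same-name records merge even without overlap", {
  layer <- ts_vector(list(
    pa_feature(rect_ring(0, 0, 1000, 1000), "Twin", 1980),
    pa_feature(rect_ring(5000, 0, 6000, 1000), "Twin", 1980)))
  out <- filter_pas(layer, quiet = TRUE)
  expect_equal(length(out), 1L)
  expect_equal(feature_attr(out, "n_members"), 2)
})

mk_td_scene <- function(vals, hl = NULL) {
  n <- nrow(vals)
  td <- ts_raster(vals, px = 1000)
  grid <- build_grid(raster_extent(td), cell_size_km = 1)
  cls <- classify_threat(td)
  list(td = td, grid = grid, levels = cls$levels, hl = hl)
}

test_that("zonal means average threatened cells by centre membership", {
  vals <- matrix(0, 4, 4)
  vals[1, 1:3] <- c(10, 20, 30)
  sc <- mk_td_scene(vals)
  zones <- ts_vector(list(list(
    geometry = ts_geom(rect_ring(0, 0, 4000, 4000)),
    attributes = list(name = "Z"))))
  zs <- zonal_summary(sc$td, sc$levels, zones, sc$grid)
  expect_equal(zs$mean_td, 20)
  expect_equal(zs$threatened_area_km2, 3)
  expect_equal(zs$zone_area_km2, 16)
  # a zone with no cells is reported missing, not zero
  far <- ts_vector(list(list(geometry = ts_geom(rect_ring(9e5, 0, 9.1e5, 1000)),
                             attributes = list(name = "empty"))))
  zs2 <- zonal_summary(sc$td, sc$levels, far, sc$grid)
  expect_equal(zs2$n_cells, 0L)
  expect_true(is.na(zs2$mean_td))
})

test_that("stratified means and D come from the highland split", {
  vals <- matrix(0, 4, 4)
  vals[1, ] <- 12; vals[2, ] <- 10
  hl <- matrix(NA_integer_, 4, 4)
  hl[1, ] <- 1L; hl[2, ] <- 0L
  sc <- mk_td_scene(vals)
  zs <- zonal_summary(sc$td, sc$levels, NULL, sc$grid, highland = hl)
  expect_equal(zs$mean_td_highland, 12)
  expect_equal(zs$mean_td_lowland, 10)
  expect_equal(zs$D, 2)
})

test_that("level areas and proportions use the threatened-area denominator", {
  # 100 threatened cells: 10 high, 20 moderate, 70 low
  vals <- matrix(0, 10, 10)
  vals[] <- c(rep(50, 10), rep(20, 20), rep(5, 70))
  td <- ts_raster(vals, px = 1000)
  grid <- build_grid(raster_extent(td), cell_size_km = 1)
  lev_vals <- matrix(0L, 10, 10)
  lev_vals[] <- c(rep(3L, 10), rep(2L, 20), rep(1L, 70))
  levels <- ts_raster(lev_vals, px = 1000, nodata = 255, integer_values = TRUE)
  zs <- level_area_stats(levels, NULL, grid, td = td)
  expect_equal(c(zs$area_high_km2, zs$area_moderate_km2, zs$area_low_km2),
               c(10, 20, 70))
  expect_equal(c(zs$prop_high, zs$prop_moderate, zs$prop_low), c(10, 20, 70))
  expect_equal(zs$prop_low + zs$prop_moderate + zs$prop_high, 100)
  expect_equal(zs$threatened_area_km2, 100)
})

test_that("per-level proportions always sum to 100 on random scenarios", {
  set.seed(14)
  for (rep in 1:25) {
    vals <- matrix(rexp(100) * rbinom(100, 1, 0.6), 10, 10)
    if (sum(vals > 0) < 3) next
    sc <- mk_td_scene(vals)
    zs <- suppressWarnings(
      zonal_summary(sc$td, sc$levels, NULL, sc$grid))
    expect_equal(zs$prop_low + zs$prop_moderate + zs$prop_high, 100)
    expect_equal(zs$area_low_km2 + zs$area_moderate_km2 + zs$area_high_km2,
                 zs$threatened_area_km2)
  }
})

test_that("zonal means match brute-force centre membership on random zones", {
  set.seed(15)
  vals <- matrix(rexp(144), 12, 12)
  sc <- mk_td_scene(vals)
  ctr <- cell_centers(sc$grid)
  for (rep in 1:5) {
    x <- runif(1, 0, 8000); y <- runif(1, 0, 8000)
    ring <- ellipse_ring(x, y, runif(1, 1500, 4000), runif(1, 1500, 4000))
    zones <- ts_vector(list(list(geometry = ts_geom(ring),
                                 attributes = list(name = "R"))))
    zs <- zonal_summary(sc$td, sc$levels, zones, sc$grid)
    inside <- points_in_geom(ctr[, 1], ctr[, 2], ts_geom(ring))
    tdv <- as.vector(t(vals))[inside]
    tdv <- tdv[tdv > 0]
    if (length(tdv)) expect_equal(zs$mean_td, mean(tdv)) else
      expect_true(is.na(zs$mean_td))
  }
})

test_that("disjoint zones add: union areas equal the sum of parts", {
  vals <- matrix(rexp(64, 0.2), 8, 8)
  sc <- mk_td_scene(vals)
  zA <- ts_geom(rect_ring(0, 4000, 8000, 8000))      # top half
  zB <- ts_geom(rect_ring(0, 0, 8000, 4000))         # bottom half
  zU <- ts_geom(rect_ring(0, 0, 8000, 8000))
  zones <- ts_vector(list(
    list(geometry = zA, attributes = list(name = "A")),
    list(geometry = zB, attributes = list(name = "B")),
    list(geometry = zU, attributes = list(name = "U"))))
  zs <- zonal_summary(sc$td, sc$levels, zones, sc$grid)
  for (col in c("area_low_km2", "area_moderate_km2", "area_high_km2",
                "threatened_area_km2", "zone_area_km2"))
    expect_equal(zs[zs$zone == "A", col] + zs[zs$zone == "B", col],
                 zs[zs$zone == "U", col])
})

test_that("PA and non-PA cells decompose the continental level areas exactly", {
  cfg <- tiny_cfg(seed = 71, n_species = 10)
  sc <- simulate_scenario(cfg)
  thr <- filter_threatened(sc$species, quiet = TRUE)
  ps <- extract_patches(suppressMessages(detect_expansion(sc$t0, sc$t1)),
                        footprints = FALSE)
  d <- compute_density_surfaces(sc$grid, ps, thr)
  td <- threat_degree(normalize_surface(d$N), normalize_surface(d$A),
                      normalize_surface(d$T))
  cls <- classify_threat(td)
  pas <- filter_pas(sc$pas, quiet = TRUE)
  continent <- zonal_summary(td, cls$levels, NULL, sc$grid)
  pa_rows <- zonal_summary(td, cls$levels, pas, sc$grid)
  # complement: cells outside every PA
  ctr <- cell_centers(sc$grid)
  in_any <- rep(FALSE, nrow(ctr))
  for (f in pas$features)
    in_any <- in_any | points_in_geom(ctr[, 1], ctr[, 2], f$geometry)
  # PA zones can overlap cell-wise only if merged groups overlap; they do not
  for (col in c("area_low_km2", "area_moderate_km2", "area_high_km2",
                "threatened_area_km2")) {
    pa_total <- sum(pa_rows[[col]], na.rm = TRUE)
    expect_lte(pa_total, continent[[col]] + 1e-9)
  }
  # exact decomposition for the threatened area via the centre rule
  v <- raster_values_masked(td)
  thr_cells <- !is.na(v) & v > 0
  areas <- cell_areas_km2(sc$grid)
  inside_mat <- matrix(in_any, sc$grid$nrow, sc$grid$ncol, byrow = TRUE)
  expect_equal(sum(pa_rows$threatened_area_km2, na.rm = TRUE),
               sum(areas[thr_cells & inside_mat]))
  expect_equal(continent$threatened_area_km2,
               sum(areas[thr_cells & inside_mat]) +
                 sum(areas[thr_cells & !inside_mat]))
})
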