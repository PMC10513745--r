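# The seeded scenario generator and its ground-truth manifest.

test_that("identical configurations reproduce identical outputs", {
  cfg <- tiny_cfg(seed = 17)
  d1 <- generate_dem(cfg); d2 <- generate_dem(cfg)
  expect_identical(d1$values, d2$values)
  lc1 <- generate_landcover_pair(cfg, d1)
  lc2 <- generate_landcover_pair(cfg, d2)
  expect_identical(lc1$t1$values, lc2$t1$values)
  expect_identical(lc1$truth$pixel_sets, lc2$truth$pixel_sets)
  s1 <- generate_species_ranges(cfg); s2 <- generate_species_ranges(cfg)
  expect_identical(s1$range, s2$range)
  p1 <- generate_pas(cfg); p2 <- generate_pas(cfg)
  expect_identical(feature_attr(p1, "status_year"), feature_attr(p2, "status_year"))
})

test_that("the default terrain populates every relief band", {
  dem <- generate_dem(tiny_cfg())
  expect_true(any(dem$values > 1500))
  expect_true(any(dem$values < 1000))
  expect_true(all(dem$values >= 0))
  rel <- classify_relief(dem, compute_slope(dem))
  expect_setequal(unique(as.vector(rel$values)), unname(RELIEF_CODES))
})

test_that("flat terrain classifies entirely as lowland", {
  cfg <- tiny_cfg(dem_relief_amplitude = 0, dem_ridge_amplitude = 0,
                  dem_base = 500)
  dem <- generate_dem(cfg)
  expect_true(all(dem$values == 500))
  rel <- classify_relief(dem, compute_slope(dem))
  expect_true(all(rel$values == RELIEF_CODES[["lowland"]]))
})

test_that("zero expansion fraction leaves the epochs identical", {
  cfg <- tiny_cfg(expansion_fraction = 0)
  lc <- generate_landcover_pair(cfg, generate_dem(cfg))
  expect_identical(lc$t0$values, lc$t1$values)
  expect_equal(nrow(lc$truth$patches), 0L)
})

test_that("planted patches are 8-disconnected: component count equals plant count", {
  for (seed in c(3, 21, 77)) {
    cfg <- tiny_cfg(seed = seed, n_patches = 3)
    lc <- generate_landcover_pair(cfg, generate_dem(cfg))
    expect_equal(nrow(lc$truth$patches), 3L)
    oracle <- floodfill_label(lc$truth$planted_mask * 1L)
    expect_equal(max(oracle), 3L)
    # the planted pixel sets are exactly the oracle components
    expect_identical(partition_signature(oracle),
                     unname(lapply(lc$truth$pixel_sets, as.integer)[
                       order(vapply(lc$truth$pixel_sets, min, 0))]))
  }
})

test_that("expansion avoids highland when the bias is zero", {
  cfg <- tiny_cfg(seed = 5, highland_bias = 0, n_patches = 6)
  dem <- generate_dem(cfg)
  lc <- generate_landcover_pair(cfg, dem)
  hl <- raster_values_masked(highland_mask(classify_relief(dem, compute_slope(dem))))
  planted <- which(lc$truth$planted_mask)
  expect_gt(length(planted), 0)
  expect_true(all(hl[planted] == 0))
})

test_that("expansion pixels convert only non-human land to human codes", {
  cfg <- tiny_cfg(seed = 11)
  lc <- generate_landcover_pair(cfg, generate_dem(cfg))
  changed <- which(lc$t0$values != lc$t1$values)
  expect_identical(sort(changed), unlist(lapply(lc$truth$pixel_sets, sort))[
    order(unlist(lc$truth$pixel_sets))])
  expect_true(all(lc$t1$values[changed] %in% HUMAN_CODES))
  expect_false(any(lc$t0$values[changed] %in% HUMAN_CODES))
})

test_that("species generator honours the category mix and plants duplicates", {
  cfg <- tiny_cfg(n_species = 40, dup_binomial_fraction = 0.2)
  sp <- generate_species_ranges(cfg)
  expect_equal(length(sp), 48L)                       # 40 + 8 duplicates
  expect_gt(sum(duplicated(sp$binomial)), 0)
  expect_true(all(sp$category %in% c("CR", "EN", "VU", "NT", "LC")))
  thr <- filter_threatened(sp, quiet = TRUE)
  expect_true(length(thr) <= 40)
})

test_that("PA generator plants pre/post-2000 years, missing years and points", {
  cfg <- tiny_cfg(n_pas = 20, pa_pre2000_fraction = 0.5,
                  pa_missing_year_fraction = 0.15, pa_point_fraction = 0.15)
  pas <- generate_pas(cfg)
  yrs <- suppressWarnings(as.numeric(feature_attr(pas, "status_year")))
  types <- vapply(pas$features, function(f) f$geometry$type, "")
  expect_equal(length(pas), 20L)
  expect_equal(sum(types == "point"), 3L)
  expect_equal(sum(is.na(yrs)), 3L)
  expect_true(any(yrs < 2000, na.rm = TRUE) && any(yrs > 2000, na.rm = TRUE))
})

test_that("per-cell truth equals an independent brute-force recomputation", {
  cfg <- tiny_cfg(seed = 29, n_species = 10)
  sc <- simulate_scenario(cfg)
  thr <- filter_threatened(sc$species, quiet = TRUE)
  mask <- suppressMessages(detect_expansion(sc$t0, sc$t1))
  ps <- extract_patches(mask, footprints = FALSE)
  oracle <- brute_density(sc$grid, ps, thr)
  pc <- sc$truth$per_cell
  cov <- !is.na(pc$N)                      # cells holding pixel centres
  expect_identical(as.integer(t(oracle$N))[cov], pc$N[cov])
  expect_equal(as.vector(t(oracle$A))[cov], pc$A[cov])
  expect_identical(as.integer(t(oracle$T))[cov], pc$T[cov])
  expect_true(all(oracle$N[t(matrix(!cov, sc$grid$ncol))] == 0L))
})

test_that("configuration validation rejects out-of-range parameters", {
  expect_error(tiny_cfg(expansion_fraction = 1.5), "fractions")
  expect_error(tiny_cfg(category_mix = c(CR = 0.5, EN = 0.2, VU = 0.1,
                                         NT = 0.1, LC = 0.05)), "sum to 1")
  expect_error(scenario_config(extent_km = 0.1, resolution = 30), "10x10")
  expect_error(tiny_cfg(highland_bias = -1), "non-negative")
})

test_that("oversized expansion demands are refused", {
  expect_error(
    generate_landcover_pair(tiny_cfg(expansion_fraction = 0.9),
                            generate_dem(tiny_cfg(expansion_fraction = 0.9))),
    "no placement possible")
})
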