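# The analysis grid, density surfaces, normalization, the geometric-mean
# index, level classification and the highland-lowland difference.

test_that("grid tessellation counts and clips cells as specified", {
  g <- build_grid(list(x0 = 0, y0 = 10000, width = 10000, height = 10000))
  expect_equal(g$nrow * g$ncol, 100L)
  expect_true(all(cell_areas_km2(g) == 1))

  g2 <- build_grid(list(x0 = 0, y0 = 10000, width = 10500, height = 10000))
  expect_equal(g2$nrow * g2$ncol, 110L)
  a <- cell_areas_km2(g2)
  expect_equal(unique(a[, 11]), 0.5)      # clipped rightmost column
  expect_equal(sum(a), 105)

  # cell (0,0) covers [x0, x0+1000) x (y0-1000, y0]
  r <- cell_ring(g, 1, 1)
  expect_equal(range(r[, 1]), c(0, 1000))
  expect_equal(range(r[, 2]), c(9000, 10000))
  expect_error(build_grid(list(x0 = 0, y0 = 1, width = 1, height = 1),
                          cell_size_km = 0), "positive")
})

mk_label_scene <- function(mask, px = 30) {
  ps <- extract_patches(mk_mask(mask, px = px), footprints = FALSE)
  grid <- build_grid(raster_extent(ps$label_raster), cell_size_km = 1)
  list(ps = ps, grid = grid)
}

test_that("density surfaces follow pixel-centre membership and conserve area", {
  m <- matrix(0L, 80, 80)                  # 2.4 km -> 3x3 grid, edges clipped
  m[5:29, 5:44] <- 1L                      # 25 x 40 = 1000 px in one patch
  sc <- mk_label_scene(m)
  expect_equal(sc$grid$nrow, 3L)
  expect_equal(cell_areas_km2(sc$grid)[3, 3], 0.4 * 0.4)
  d <- compute_density_surfaces(sc$grid, sc$ps)
  # patch spans columns 5..44 at 30 m: centres in [135, 1305] -> two cells
  expectN <- matrix(0L, 3, 3); expectN[1, 1:2] <- 1L
  expect_equal(d$N$values, expectN)
  # A split by pixel membership: cols 5..33 centres < 1000 m (29 px/row)
  expect_equal(d$A$values[1, 1], 25 * 29 * 0.0009)
  expect_equal(d$A$values[1, 2], 25 * 11 * 0.0009)
  expect_equal(sum(d$A$values), 1000 * 0.0009)       # conservation: 0.9 km2
  expect_equal(d$T$values, matrix(0L, 3, 3))         # no species given
})

test_that("cells without expansion get zero densities", {
  m <- matrix(0L, 80, 80); m[3, 3] <- 1L
  sc <- mk_label_scene(m)
  d <- compute_density_surfaces(sc$grid, sc$ps)
  expect_equal(sum(d$N$values), 1L)
  expect_equal(d$N$values[2, 2], 0L)
  expect_equal(d$A$values[2, 2], 0)
  # invariant N = 0 => A = 0 and T = 0
  z <- d$N$values == 0L
  expect_true(all(d$A$values[z] == 0) && all(d$T$values[z] == 0L))
})

test_that("density surfaces match the brute-force per-pixel oracle", {
  set.seed(44)
  cfg <- tiny_cfg(seed = 59, n_species = 10)
  sc <- simulate_scenario(cfg)
  thr <- filter_threatened(sc$species, quiet = TRUE)
  ps <- extract_patches(suppressMessages(detect_expansion(sc$t0, sc$t1)),
                        footprints = FALSE)
  d <- compute_density_surfaces(sc$grid, ps, thr)
  oracle <- brute_density(sc$grid, ps, thr)
  expect_identical(d$N$values, oracle$N)
  expect_equal(d$A$values, oracle$A)
  expect_identical(d$T$values, oracle$T)
})

test_that("normalization maps min to 0, max to 100, midpoint to 50", {
  X <- mk_raster(matrix(c(2, 6, 10, 4), 2, 2))
  n <- normalize_surface(X)
  expect_equal(n$values, matrix(c(0, 50, 100, 25), 2, 2))
  expect_warning(n0 <- normalize_surface(mk_raster(matrix(3, 2, 2))),
                 "degenerate")
  expect_true(all(n0$values == 0))
})

test_that("normalization is invariant under positive rescaling", {
  set.seed(2)
  X <- mk_raster(matrix(rpois(100, 4), 10, 10))
  for (k in c(0.5, 3, 1000)) {
    Xk <- mk_raster(X$values * k)
    expect_equal(normalize_surface(Xk)$values, normalize_surface(X)$values,
                 tolerance = 1e-12)
  }
})

test_that("the threat degree is the cellwise geometric mean", {
  dn <- mk_raster(matrix(c(100, 0, 12.5, 30), 2, 2), px = 1000)
  da <- mk_raster(matrix(c(100, 50, 50, 30), 2, 2), px = 1000)
  dt <- mk_raster(matrix(c(100, 70, 8, 30), 2, 2), px = 1000)
  td <- threat_degree(dn, da, dt)
  expect_equal(td$values[1, 1], 100)
  expect_equal(td$values[2, 1], 0)                      # zero propagates
  expect_equal(td$values[1, 2], 5000^(1 / 3))           # 17.0998 (12.5*50*8)
  expect_equal(td$values[1, 2], 17.0998, tolerance = 1e-4)
  expect_equal(td$values[2, 2], 30)
  expect_error(threat_degree(mk_raster(matrix(-1, 2, 2), px = 1000), da, dt),
               "non-negative")
})

test_that("threat degree stays within [0, 100] and zero-propagates end to end", {
  cfg <- tiny_cfg(seed = 23, n_species = 10)
  sc <- simulate_scenario(cfg)
  thr <- filter_threatened(sc$species, quiet = TRUE)
  ps <- extract_patches(suppressMessages(detect_expansion(sc$t0, sc$t1)),
                        footprints = FALSE)
  d <- compute_density_surfaces(sc$grid, ps, thr)
  td <- threat_degree(normalize_surface(d$N), normalize_surface(d$A),
                      normalize_surface(d$T))
  v <- td$values
  expect_true(all(v >= 0 & v <= 100))
  expect_true(all(v[d$N$values == 0L] == 0))
})

test_that("raising one raw density never lowers that cell's TD", {
  set.seed(6)
  N <- matrix(rpois(64, 2), 8, 8); A <- matrix(rpois(64, 3), 8, 8)
  Tm <- matrix(rpois(64, 2), 8, 8)
  mk <- function(m) mk_raster(m, px = 1000)
  td0 <- threat_degree(normalize_surface(mk(N)), normalize_surface(mk(A)),
                       normalize_surface(mk(Tm)))
  # bump an interior (non-extreme) cell of N
  cand <- which(N > min(N) & N < max(N))[1]
  N2 <- N; N2[cand] <- N2[cand] + 1
  stopifnot(max(N2) == max(N))           # extremes unchanged
  td1 <- threat_degree(normalize_surface(mk(N2)), normalize_surface(mk(A)),
                       normalize_surface(mk(Tm)))
  expect_gte(td1$values[cand], td0$values[cand])
})

test_that("classification reproduces mean/SD cut-offs and partitions cells", {
  # surface engineered to a known mean and SD on the TD > 0 domain
  td <- mk_raster(matrix(c(0, 0, 10, 20, 30, 40, 0, 25, 15), 3, 3), px = 1000)
  cls <- classify_threat(td)
  x <- c(10, 20, 30, 40, 25, 15)
  expect_equal(cls$thresholds$mean, mean(x))
  expect_equal(cls$thresholds$sd, sd(x))
  expect_equal(cls$thresholds$low_cut, mean(x) + 0.5 * sd(x))
  expect_equal(cls$thresholds$high_cut, mean(x) + 1.5 * sd(x))
  lv <- cls$levels$values
  expect_equal(sum(lv %in% 1:3), 6L)                   # partition of domain
  expect_equal(sum(lv == 0L), 3L)                      # no-threat cells
})

test_that("published-style cut-offs invert to the map statistics behind them", {
  st <- solve_threshold_stats(11.74, 17.82)
  expect_equal(unname(st["mean"]), 8.70, tolerance = 1e-12)
  expect_equal(unname(st["sd"]), 6.08, tolerance = 1e-12)
  # round trip with the forward formulas
  cuts <- threat_thresholds(st[["mean"]], st[["sd"]])
  expect_equal(unname(cuts), c(11.74, 17.82))
})

test_that("moderate interval is closed at both cut-offs", {
  td <- mk_raster(matrix(c(5, 11.74, 11.73, 14, 17.82, 17.83, 30, 0, 1),
                         3, 3), px = 1000)
  lv <- apply_threat_levels(td, 11.74, 17.82)$values
  expect_equal(unname(lv[1:3, 1]),
               unname(THREAT_LEVELS[c("low", "moderate", "low")]))
  expect_equal(unname(lv[1:3, 2]),
               unname(THREAT_LEVELS[c("moderate", "moderate", "high")]))
  expect_equal(unname(lv[1:2, 3]),
               unname(THREAT_LEVELS[c("high", "none")]))  # TD=0 unclassified
  expect_warning(classify_threat(mk_raster(matrix(5, 2, 2), px = 1000)),
                 "zero spread")
})

test_that("highland-lowland difference recovers planted stratum means", {
  td <- mk_raster(matrix(c(12, 12, 10, 10), 2, 2), px = 1000)
  hl <- matrix(c(1L, 1L, 0L, 0L), 2, 2)
  expect_equal(highland_lowland_difference(td, hl), 2)
  expect_equal(highland_lowland_difference(td, matrix(1L, 2, 2)), NA_real_)
  same <- mk_raster(matrix(8, 2, 2), px = 1000)
  expect_equal(highland_lowland_difference(same, hl, domain = "all"), 0)
  # printed-style strata means subtract as stated: 8.3 - 8.9 = -0.6
  td2 <- mk_raster(matrix(c(8.3, 8.3, 8.9, 8.9), 2, 2), px = 1000)
  expect_equal(highland_lowland_difference(td2, hl), -0.6)
})
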