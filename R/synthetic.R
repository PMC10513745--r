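# Seeded synthetic landscapes: DEM, land-cover epoch pair with planted
# expansion patches, species ranges, protected areas and country zones,
# together with an exact ground-truth manifest, standing in for the
# continental DEM / land-cover / Red List / PA sources.

#' Scenario configuration
#'
#' One seeded configuration drives every generator; identical configurations
#' produce byte-identical outputs. A single root seed feeds fixed-order
#' sub-streams (terrain, land cover, species, protected areas, zones), so
#' adding draws to a later stage never perturbs an earlier one.
#'
#' @param seed Integer root seed.
#' @param extent_km Square extent edge (km).
#' @param resolution Pixel size (m).
#' @param n_species Number of species range records before duplication.
#' @param category_mix Proportions over CR/EN/VU/NT/LC, summing to 1.
#' @param expansion_fraction Share of non-human pixels converted between the
#'   epochs.
#' @param highland_bias Relative propensity of expansion in highland cells
#'   (1 = terrain-neutral, 0 = lowland only).
#' @param clustering Patch cohesion in `[0, 1]` (1 = compact).
#' @param n_pas Number of protected-area records.
#' @param pa_pre2000_fraction Share of PAs with status year before 2000.
#' @param pa_missing_year_fraction Share of PAs with no status year.
#' @param pa_point_fraction Share of PAs emitted as point features.
#' @param n_zones Number of country-like rectangular zones.
#' @param n_patches Exact number of expansion patches to plant, or NULL to
#'   derive patch count from `expansion_fraction`.
#' @param dup_binomial_fraction Share of extra records duplicating an
#'   existing binomial (exercises deduplication).
#' @param richness_gradient Strength of the species-richness gradient toward
#'   the south-west corner (0 = uniform).
#' @param t0_human_fraction Share of the map seeded as human land already in
#'   the first epoch.
#' @param dem_base,dem_relief_amplitude,dem_ridge_amplitude Elevation model:
#'   base level, correlated-field amplitude, ridge amplitude (m).
#' @param mean_patch_px Mean planted patch size (pixels).
#' @return A `ts_scenario_config` list.
#' @export
scenario_config <- function(seed = 1,
                            extent_km = 60,
                            resolution = 30,
                            n_species = 20,
                            category_mix = c(CR = 0.10, EN = 0.20, VU = 0.25,
                                             NT = 0.15, LC = 0.30),
                            expansion_fraction = 0.01,
                            highland_bias = 1,
                            clustering = 0.8,
                            n_pas = 12,
                            pa_pre2000_fraction = 0.7,
                            pa_missing_year_fraction = 0.1,
                            pa_point_fraction = 0.1,
                            n_zones = 4,
                            n_patches = NULL,
                            dup_binomial_fraction = 0.15,
                            richness_gradient = 1,
                            t0_human_fraction = 0.05,
                            dem_base = 200,
                            dem_relief_amplitude = 500,
                            dem_ridge_amplitude = 1600,
                            mean_patch_px = 150) {
  cfg <- as.list(environment())
  fr <- c(expansion_fraction, pa_pre2000_fraction, pa_missing_year_fraction,
          pa_point_fraction, clustering, dup_binomial_fraction,
          t0_human_fraction)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (abs(sum(category_mix) - 1) > 1e-9) stop("category_mix must sum to 1")
  if (highland_bias < 0) stop("highland_bias must be non-negative")
  npx <- extent_km * 1000 / resolution
  if (npx < 10) stop("extent/resolution must yield at least 10x10 pixels")
  cfg$n_px <- as.integer(round(npx))
  class(cfg) <- "ts_scenario_config"
  cfg
}

# fixed-order sub-seeds from the root seed
sub_seeds <- function(cfg) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  stats::setNames(sample.int(.Machine$integer.max - 1L, 6),
                  c("dem", "landcover", "species", "pas", "zones", "extra"))
}

bilinear_upsample <- function(coarse, nr, nc) {
  k <- nrow(coarse)
  xi <- seq(1, k, length.out = nr)
  yi <- seq(1, ncol(coarse), length.out = nc)
  i0 <- pmin(floor(xi), k - 1); fi <- xi - i0
  j0 <- pmin(floor(yi), ncol(coarse) - 1); fj <- yi - j0
  a <- coarse[cbind(rep(i0, nc), rep(j0, each = nr))]
  b <- coarse[cbind(rep(i0 + 1, nc), rep(j0, each = nr))]
  cc <- coarse[cbind(rep(i0, nc), rep(j0 + 1, each = nr))]
  d <- coarse[cbind(rep(i0 + 1, nc), rep(j0 + 1, each = nr))]
  fim <- rep(fi, nc); fjm <- rep(fj, each = nr)
  matrix(a * (1 - fim) * (1 - fjm) + b * fim * (1 - fjm) +
         cc * (1 - fim) * fjm + d * fim * fjm, nr, nc)
}

#' Generate a synthetic DEM
#'
#' A smooth correlated field (bilinear interpolation of a coarse Gaussian
#' grid) over a base level, plus two sharp ridge features, clamped at sea
#' level. Under the default configuration the elevation range covers all
#' four relief bands (below 1,000 m up to above 1,500 m).
#'
#' @param cfg A [scenario_config()].
#' @return A float [ts_raster] of elevation (m).
#' @export
generate_dem <- function(cfg) {
  seeds <- sub_seeds(cfg)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seeds[["dem"]])
  n <- cfg$n_px
  if (n < 2) stop("degenerate extent")
  coarse <- matrix(stats::rnorm(64), 8, 8)
  z <- cfg$dem_base + cfg$dem_relief_amplitude * bilinear_upsample(coarse, n, n)

  if (cfg$dem_ridge_amplitude > 0) {
    xs <- matrix(rep(seq_len(n), each = n), n, n)   # col index
    ys <- matrix(rep(seq_len(n), times = n), n, n)  # row index
    for (r in 1:2) {
      ang <- stats::runif(1, 0, pi)
      cx <- stats::runif(1, 0.25, 0.75) * n
      cy <- stats::runif(1, 0.25, 0.75) * n
      d <- abs((xs - cx) * sin(ang) - (ys - cy) * cos(ang))
      along <- (xs - cx) * cos(ang) + (ys - cy) * sin(ang)
      w <- 0.035 * n
      taper <- exp(-(along / (0.45 * n))^2)
      z <- z + cfg$dem_ridge_amplitude * exp(-(d / w)^2) * taper / r
    }
  }
  z[z < 0] <- 0
  ts_raster(z, x0 = 0, y0 = n * cfg$resolution,
            px = cfg$resolution, nodata = NA)
}

# stratum weight per pixel: lowland 1, highland `highland_bias`
.strata_weights <- function(cfg, dem) {
  relief <- classify_relief(dem, compute_slope(dem))
  hl <- raster_values_masked(highland_mask(relief))
  w <- matrix(1, nrow(hl), ncol(hl))
  w[hl == 1] <- cfg$highland_bias
  w[is.na(hl)] <- 0
  w
}

#' Generate the land-cover epoch pair with planted expansion
#'
#' Epoch `t0` carries non-human classes (forest, grassland, bareland, water)
#' driven by elevation plus seeded human blocks; `t1` equals `t0` except for
#' the planted expansion patches, which flip to cropland (10) or artificial
#' surface (80). Patches are grown pixel-by-pixel with cohesion `clustering`,
#' seeded and grown with per-stratum propensity `highland_bias`, and planted
#' pairwise 8-disconnected (a one-pixel halo separates them), so the planted
#' patch count is exactly the number of 8-connected components.
#'
#' @param cfg A [scenario_config()].
#' @param dem The DEM from [generate_dem()].
#' @return List: `t0`, `t1` (integer rasters), `truth` (list with
#'   `patches` data.frame id/pixel_count/area_km2, `pixel_sets` list of
#'   linear pixel indices (column-major), `planted_mask` matrix).
#' @export
generate_landcover_pair <- function(cfg, dem) {
  seeds <- sub_seeds(cfg)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seeds[["landcover"]])
  n <- cfg$n_px
  e <- dem$values
  w <- .strata_weights(cfg, dem)

  # epoch-one land cover from elevation + a smooth noise field
  noise <- bilinear_upsample(matrix(stats::rnorm(36), 6, 6), n, n)
  t0 <- matrix(20L, n, n)                       # forest
  t0[noise > 0.6 | e > 900] <- 30L              # grassland
  t0[e > 1400] <- 90L                           # bareland
  t0[noise < -1.1 & e < 400] <- 60L             # water

  # seeded epoch-one human land: a few lowland blocks
  n_h <- max(0L, round(cfg$t0_human_fraction * n * n))
  if (n_h > 0) {
    blocks <- max(1L, round(n_h / (0.002 * n * n + 100)))
    side <- max(2L, round(sqrt(n_h / blocks)))
    low <- which(w > 0 & e < 800)
    for (b in seq_len(blocks)) {
      s <- low[sample.int(length(low), 1)]
      si <- ((s - 1L) %% n) + 1L; sj <- ((s - 1L) %/% n) + 1L
      ii <- si:min(n, si + side - 1L); jj <- sj:min(n, sj + side - 1L)
      t0[ii, jj] <- 10L
    }
  }

  human0 <- t0 %in% HUMAN_CODES
  dim(human0) <- dim(t0)
  non_human <- sum(!human0 & t0 != 60L)

  sizes <- integer(0)
  if (is.null(cfg$n_patches)) {
    target <- round(cfg$expansion_fraction * non_human)
    while (sum(sizes) < target) {
      s <- 1L + stats::rpois(1, cfg$mean_patch_px - 1)
      sizes <- c(sizes, min(s, target - sum(sizes)))
    }
  } else if (cfg$n_patches > 0) {
    sizes <- 1L + stats::rpois(cfg$n_patches, cfg$mean_patch_px - 1)
  }
  if (length(sizes) > 0 && sum(sizes) > 0.5 * non_human)
    stop("expansion_fraction too large: no placement possible")

  # blocked: epoch-one human, water, zero-weight strata; grows with halos
  blocked <- human0 | t0 == 60L | w == 0
  planted <- matrix(FALSE, n, n)
  pixel_sets <- list()
  neigh8 <- expand.grid(di = -1:1, dj = -1:1)
  neigh8 <- neigh8[!(neigh8$di == 0 & neigh8$dj == 0), ]

  for (target_px in sizes) {
    free <- which(!blocked)
    if (length(free) == 0) break
    seed_px <- free[sample.int(length(free), 1,
                               prob = w[free] / sum(w[free]))]
    members <- seed_px
    member_set <- new.env(hash = TRUE)
    assign(as.character(seed_px), TRUE, envir = member_set)
    frontier <- integer(0)
    add_frontier <- function(px, frontier) {
      pi_ <- ((px - 1L) %% n) + 1L; pj <- ((px - 1L) %/% n) + 1L
      ni <- pi_ + neigh8$di; nj <- pj + neigh8$dj
      okn <- ni >= 1 & ni <= n & nj >= 1 & nj <= n
      cand <- (nj[okn] - 1L) * n + ni[okn]
      cand <- cand[!blocked[cand] & w[cand] > 0]
      cand <- cand[!vapply(as.character(cand), exists, TRUE, envir = member_set)]
      unique(c(frontier, cand))
    }
    frontier <- add_frontier(seed_px, frontier)
    while (length(members) < target_px && length(frontier) > 0) {
      if (stats::runif(1) < cfg$clustering) {
        nxt <- frontier[1]             # oldest frontier cell: compact growth
      } else {
        nxt <- frontier[sample.int(length(frontier), 1,
                                   prob = w[frontier] / sum(w[frontier]))]
      }
      frontier <- frontier[frontier != nxt]
      members <- c(members, nxt)
      assign(as.character(nxt), TRUE, envir = member_set)
      frontier <- add_frontier(nxt, frontier)
    }
    planted[members] <- TRUE
    # halo: block members and their 8-neighbourhood so patches stay disjoint
    mi <- ((members - 1L) %% n) + 1L; mj <- ((members - 1L) %/% n) + 1L
    for (k in seq_len(nrow(neigh8))) {
      hi <- mi + neigh8$di[k]; hj <- mj + neigh8$dj[k]
      okh <- hi >= 1 & hi <= n & hj >= 1 & hj <= n
      blocked[(hj[okh] - 1L) * n + hi[okh]] <- TRUE
    }
    blocked[members] <- TRUE
    pixel_sets[[length(pixel_sets) + 1]] <- sort(members)
  }

  t1 <- t0
  codes <- c(10L, 80L)
  for (k in seq_along(pixel_sets))
    t1[pixel_sets[[k]]] <- codes[1 + (stats::runif(1) > 0.5)]

  area_px <- cfg$resolution^2 / 1e6
  counts <- vapply(pixel_sets, length, 0L)
  mk <- function(v) ts_raster(v, x0 = 0, y0 = n * cfg$resolution,
                              px = cfg$resolution, nodata = 255,
                              integer_values = TRUE)
  list(t0 = mk(t0), t1 = mk(t1),
       truth = list(patches = data.frame(id = seq_along(pixel_sets),
                                         pixel_count = counts,
                                         area_km2 = counts * area_px),
                    pixel_sets = pixel_sets,
                    planted_mask = planted))
}

#' Generate synthetic species range records
#'
#' Elliptical range polygons with areas spanning roughly 1-50% of the
#' extent, categories drawn from `category_mix`, an optional richness
#' gradient toward the south-west corner, and a share of duplicate-binomial
#' records to exercise deduplication.
#'
#' @param cfg A [scenario_config()].
#' @param extent Extent list ([raster_extent()]); defaults to the
#'   configuration's square extent.
#' @return A `ts_species` of raw (unfiltered) records.
#' @export
generate_species_ranges <- function(cfg, extent = NULL) {
  seeds <- sub_seeds(cfg)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seeds[["species"]])
  if (is.null(extent))
    extent <- list(x0 = 0, y0 = cfg$extent_km * 1000,
                   width = cfg$extent_km * 1000,
                   height = cfg$extent_km * 1000)
  n <- cfg$n_species
  if (n == 0) return(species_set(character(0), character(0), list()))
  groups <- c("mammal", "amphibian", "reptile", "bird", "plant")
  binomial <- sprintf("Synthetica species%02d", seq_len(n))
  category <- sample(names(cfg$category_mix), n, replace = TRUE,
                     prob = cfg$category_mix)
  group <- sample(groups, n, replace = TRUE)

  one_range <- function() {
    # richness gradient: bias centres toward the south-west (low x, low y)
    g <- cfg$richness_gradient
    cx <- extent$x0 + extent$width * stats::rbeta(1, 1, 1 + g)
    cy <- extent$y0 - extent$height + extent$height * stats::rbeta(1, 1, 1 + g)
    afrac <- exp(stats::runif(1, log(0.01), log(0.5)))
    area <- afrac * extent$width * extent$height
    ratio <- stats::runif(1, 0.4, 1)
    rx <- sqrt(area / (pi * ratio)); ry <- rx * ratio
    ts_geom(ellipse_ring(cx, cy, rx, ry, angle = stats::runif(1, 0, pi)))
  }
  range <- replicate(n, one_range(), simplify = FALSE)

  n_dup <- round(cfg$dup_binomial_fraction * n)
  if (n_dup > 0) {
    src <- sample.int(n, n_dup, replace = TRUE)
    binomial <- c(binomial, binomial[src])
    category <- c(category, category[src])
    group <- c(group, group[src])
    range <- c(range, replicate(n_dup, one_range(), simplify = FALSE))
  }
  species_set(binomial, category, range, group)
}

#' Generate a synthetic protected-area layer
#'
#' Elliptical PA polygons with `name` and `status_year` attributes:
#' `pa_pre2000_fraction` get years before 2000, a configurable share get a
#' missing year, and a share are emitted as point features, so the PA filter
#' has every exclusion rule to exercise.
#'
#' @param cfg A [scenario_config()].
#' @param extent Extent list; defaults to the configuration's extent.
#' @return A [ts_vector] (mixed polygon/point geometries).
#' @export
generate_pas <- function(cfg, extent = NULL) {
  seeds <- sub_seeds(cfg)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seeds[["pas"]])
  if (is.null(extent))
    extent <- list(x0 = 0, y0 = cfg$extent_km * 1000,
                   width = cfg$extent_km * 1000,
                   height = cfg$extent_km * 1000)
  n <- cfg$n_pas
  feats <- vector("list", n)
  if (n == 0) return(ts_vector(feats))
  n_pt <- round(cfg$pa_point_fraction * n)
  n_na <- round(cfg$pa_missing_year_fraction * n)
  n_pre <- round(cfg$pa_pre2000_fraction * n)
  years <- c(sample(1950:1999, n_pre, replace = TRUE),
             sample(2001:2015, n - n_pre, replace = TRUE))
  years <- years[sample.int(n)]
  is_point <- seq_len(n) %in% sample.int(n, n_pt)
  no_year <- seq_len(n) %in% sample.int(n, n_na)
  for (k in seq_len(n)) {
    cx <- extent$x0 + stats::runif(1, 0.05, 0.95) * extent$width
    cy <- extent$y0 - stats::runif(1, 0.05, 0.95) * extent$height
    if (is_point[k]) {
      geom <- ts_point(cx, cy)
    } else {
      r <- stats::runif(1, 0.02, 0.12) * extent$width
      geom <- ts_geom(ellipse_ring(cx, cy, r, r * stats::runif(1, 0.5, 1),
                                   angle = stats::runif(1, 0, pi)))
    }
    feats[[k]] <- list(geometry = geom,
                       attributes = list(name = sprintf("PA %02d", k),
                                         status_year = if (no_year[k]) NA
                                                       else years[k]))
  }
  ts_vector(feats)
}

#' Generate country-like rectangular zones
#'
#' Splits the extent into a jittered rectangular mosaic of `n_zones` zones.
#'
#' @param cfg A [scenario_config()].
#' @param extent Extent list; defaults to the configuration's extent.
#' @return A [ts_vector] of polygons with attribute `name`.
#' @export
generate_zones <- function(cfg, extent = NULL) {
  seeds <- sub_seeds(cfg)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seeds[["zones"]])
  if (is.null(extent))
    extent <- list(x0 = 0, y0 = cfg$extent_km * 1000,
                   width = cfg$extent_km * 1000,
                   height = cfg$extent_km * 1000)
  n <- cfg$n_zones
  kx <- ceiling(sqrt(n)); ky <- ceiling(n / kx)
  jit <- function(k, len) {
    cuts <- seq(0, len, length.out = k + 1)
    if (k > 1)
      cuts[2:k] <- cuts[2:k] + stats::runif(k - 1, -0.1, 0.1) * len / k
    cuts
  }
  xc <- jit(kx, extent$width); yc <- jit(ky, extent$height)
  feats <- list()
  for (i in seq_len(ky)) for (j in seq_len(kx)) {
    if (length(feats) >= n) break
    ring <- rect_ring(extent$x0 + xc[j], extent$y0 - yc[i + 1],
                      extent$x0 + xc[j + 1], extent$y0 - yc[i])
    feats[[length(feats) + 1]] <-
      list(geometry = ts_geom(ring),
           attributes = list(name = sprintf("Country %s", LETTERS[length(feats) + 1])))
  }
  ts_vector(feats)
}

#' Simulate a complete scenario with ground truth
#'
#' Runs every generator off one configuration and derives the truth
#' manifest: planted patches and exact per-cell densities (patch count,
#' expansion area, species involvement) computed directly from the planted
#' pixel sets and range polygons, independent of the detection/labeling
#' pipeline they validate.
#'
#' @param cfg A [scenario_config()].
#' @param grid_km Analysis-grid cell size (km) for the per-cell truth.
#' @return List: `cfg`, `dem`, `t0`, `t1`, `species`, `pas`, `zones`,
#'   `grid`, `truth` (with `patches`, `pixel_sets`, `per_cell` data.frame of
#'   cell/N/A/T).
#' @export
simulate_scenario <- function(cfg, grid_km = 1) {
  dem <- generate_dem(cfg)
  lc <- generate_landcover_pair(cfg, dem)
  species <- generate_species_ranges(cfg)
  pas <- generate_pas(cfg)
  zones <- generate_zones(cfg)
  grid <- build_grid(raster_extent(dem), cell_size_km = grid_km)

  thr <- filter_threatened(species, quiet = TRUE)
  truth <- lc$truth
  truth$per_cell <- truth_per_cell(truth$pixel_sets, dem, grid, thr)
  list(cfg = cfg, dem = dem, t0 = lc$t0, t1 = lc$t1,
       species = species, pas = pas, zones = zones, grid = grid,
       truth = truth)
}

# exact per-cell N/A/T from planted pixel sets (column-major linear indices)
truth_per_cell <- function(pixel_sets, dem, grid, thr_species) {
  n <- nrow(dem$values)
  area_px <- pixel_area_km2(dem)
  Nc <- matrix(0L, grid$nrow, grid$ncol)
  Ac <- matrix(0, grid$nrow, grid$ncol)
  Tc <- matrix(0L, grid$nrow, grid$ncol)
  cellmap <- cell_index_of_pixels(dem, grid)
  all_px <- unlist(pixel_sets)
  for (s in pixel_sets) {
    ids <- unique(cellmap[s])
    ids <- ids[!is.na(ids)]
    Nc[cbind((ids - 1) %/% grid$ncol + 1, (ids - 1) %% grid$ncol + 1)] <-
      Nc[cbind((ids - 1) %/% grid$ncol + 1, (ids - 1) %% grid$ncol + 1)] + 1L
  }
  if (length(all_px)) {
    ids <- cellmap[all_px]
    ok <- !is.na(ids)
    tab <- tabulate_cells(ids[ok], grid)
    Ac <- tab * area_px
    if (length(thr_species) > 0) {
      ctr <- pixel_centers(list(values = dem$values,
                                transform = dem$transform),
                           rows = ((all_px - 1L) %% n) + 1L,
                           cols = ((all_px - 1L) %/% n) + 1L)
      for (k in seq_along(thr_species$binomial)) {
        inside <- points_in_geom(ctr[, 1], ctr[, 2], thr_species$range[[k]])
        hit <- unique(ids[inside & ok])
        Tc[cbind((hit - 1) %/% grid$ncol + 1, (hit - 1) %% grid$ncol + 1)] <-
          Tc[cbind((hit - 1) %/% grid$ncol + 1, (hit - 1) %% grid$ncol + 1)] + 1L
      }
    }
  }
  # cells holding no pixel centres at all sit outside the analysed area
  covered <- tabulate_cells(cellmap[!is.na(cellmap)], grid) > 0
  Nc[!covered] <- NA; Ac[!covered] <- NA; Tc[!covered] <- NA
  data.frame(cell = seq_len(grid$nrow * grid$ncol),
             N = as.integer(t(Nc)), A = as.vector(t(Ac)),
             T = as.integer(t(Tc)))
}
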