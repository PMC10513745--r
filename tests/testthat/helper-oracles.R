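# Independent oracles and small fixture builders. Every oracle here is a
# deliberately naive reimplementation (loops, queues, textbook formulas)
# kept free of the package's own code paths.

# BFS flood-fill labeling of a binary matrix under 8-connectivity.
floodfill_label <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  k <- 0L
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (mask[i, j] == 1L && lab[i, j] == 0L) {
      k <- k + 1L
      queue <- list(c(i, j)); lab[i, j] <- k
      while (length(queue) > 0) {
        p <- queue[[1]]; queue <- queue[-1]
        for (di in -1:1) for (dj in -1:1) {
          ni <- p[1] + di; nj <- p[2] + dj
          if (ni >= 1 && ni <= nr && nj >= 1 && nj <= nc &&
              mask[ni, nj] == 1L && lab[ni, nj] == 0L) {
            lab[ni, nj] <- k
            queue[[length(queue) + 1]] <- c(ni, nj)
          }
        }
      }
    }
  }
  lab
}

# partition signature invariant to label permutation: for each component,
# the sorted pixel indices, sorted by first pixel
partition_signature <- function(lab) {
  ids <- sort(unique(lab[lab > 0]))
  parts <- lapply(ids, function(k) sort(which(lab == k)))
  parts[order(vapply(parts, `[`, 0L, 1))]
}

# Per-pixel brute-force density surfaces: loops over every labeled pixel and
# every species, scalar point-in-polygon (ray casting, re-derived here).
brute_density <- function(grid, patches, sp) {
  lab <- patches$label_raster$values
  tr <- patches$label_raster$transform
  nr <- nrow(lab); nc <- ncol(lab)
  N <- matrix(0L, grid$nrow, grid$ncol)
  A <- matrix(0, grid$nrow, grid$ncol)
  Tm <- matrix(0L, grid$nrow, grid$ncol)
  seen_patch <- list(); seen_sp <- list()
  pt_in_ring1 <- function(x, y, ring) {
    n <- nrow(ring); inside <- FALSE; j <- n
    for (i in seq_len(n)) {
      xi <- ring[i, 1]; yi <- ring[i, 2]; xj <- ring[j, 1]; yj <- ring[j, 2]
      if ((yi > y) != (yj > y) && x < (xj - xi) * (y - yi) / (yj - yi) + xi)
        inside <- !inside
      j <- i
    }
    inside
  }
  pt_in_geom1 <- function(x, y, g) {
    for (poly in g$polys) {
      if (pt_in_ring1(x, y, poly[[1]])) {
        in_hole <- FALSE
        if (length(poly) > 1)
          for (h in poly[-1]) if (pt_in_ring1(x, y, h)) in_hole <- TRUE
        if (!in_hole) return(TRUE)
      }
    }
    FALSE
  }
  px_area <- tr[["px"]] * tr[["py"]] / 1e6
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (lab[i, j] > 0L) {
      cx <- tr[["x0"]] + (j - 0.5) * tr[["px"]]
      cy <- tr[["y0"]] - (i - 0.5) * tr[["py"]]
      gj <- floor((cx - grid$x0) / grid$cell)
      gi <- floor((grid$y0 - cy) / grid$cell)
      if (gi < 0 || gi >= grid$nrow || gj < 0 || gj >= grid$ncol) next
      gi <- gi + 1L; gj <- gj + 1L
      A[gi, gj] <- A[gi, gj] + px_area
      key <- paste(gi, gj)
      if (!(lab[i, j] %in% seen_patch[[key]])) {
        seen_patch[[key]] <- c(seen_patch[[key]], lab[i, j])
        N[gi, gj] <- N[gi, gj] + 1L
      }
      if (!is.null(sp)) for (s in seq_along(sp$binomial)) {
        if (!(s %in% seen_sp[[key]]) && pt_in_geom1(cx, cy, sp$range[[s]])) {
          seen_sp[[key]] <- c(seen_sp[[key]], s)
          Tm[gi, gj] <- Tm[gi, gj] + 1L
        }
      }
    }
  }
  list(N = N, A = A, T = Tm)
}

# Textbook Pearson r via the covariance formula.
pearson_oracle <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxx <- sum((x - mean(x))^2); syy <- sum((y - mean(y))^2)
  sxy / sqrt(sxx * syy)
}

# Monte-Carlo-free overlap oracle: dense point-grid intersection test.
grid_overlap_oracle <- function(ga, gb, n = 250) {
  bb <- geom_bbox(ga)
  bb2 <- geom_bbox(gb)
  lo_x <- max(bb["xmin"], bb2["xmin"]); hi_x <- min(bb["xmax"], bb2["xmax"])
  lo_y <- max(bb["ymin"], bb2["ymin"]); hi_y <- min(bb["ymax"], bb2["ymax"])
  if (lo_x >= hi_x || lo_y >= hi_y) return(FALSE)
  xs <- seq(lo_x, hi_x, length.out = n)
  ys <- seq(lo_y, hi_y, length.out = n)
  px <- rep(xs, times = n); py <- rep(ys, each = n)
  any(points_in_geom(px, py, ga) & points_in_geom(px, py, gb))
}

# small raster builder
mk_raster <- function(values, px = 30, nodata = NA, integer_values = FALSE) {
  ts_raster(as.matrix(values), px = px, nodata = nodata,
            integer_values = integer_values)
}

# binary mask raster builder
mk_mask <- function(mat, px = 30) {
  mk_raster(mat, px = px, nodata = 255, integer_values = TRUE)
}

# tiny scenario used across tests (8 km, fast)
tiny_cfg <- function(seed = 42, ...) {
  defaults <- list(seed = seed, extent_km = 8, n_species = 8, n_pas = 8,
                   n_zones = 4, mean_patch_px = 40,
                   expansion_fraction = 0.01)
  do.call(scenario_config, utils::modifyList(defaults, list(...)))
}
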