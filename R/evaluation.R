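# Index-suitability evaluation: spatially separated random sampling of the
# threat surface and Pearson correlations of the index against its
# components.

#' Sample the threat surface and its components
#'
#' Draws a seeded random sample of grid cells honouring a minimum spacing
#' between sample points (cell centres), then records TD and the three raw
#' densities at each point. Greedy thinning of a seeded random permutation:
#' a candidate is kept when it lies at least `interval_km` from every point
#' already kept, until `n_target` points are kept or candidates run out.
#'
#' @param td Threat-degree [ts_raster] on the analysis grid.
#' @param densities List with `N`, `A`, `T` rasters
#'   ([compute_density_surfaces()]).
#' @param grid The `ts_grid`.
#' @param interval_km Minimum spacing between samples (km).
#' @param n_target Maximum number of samples.
#' @param seed Integer seed.
#' @param domain `"threatened"` restricts candidates to cells with TD > 0
#'   (default), `"all"` uses every valid cell.
#' @return data.frame with columns x, y, TD, N, A, T.
#' @export
sample_surfaces <- function(td, densities, grid, interval_km = 3,
                            n_target = 1000, seed = 1,
                            domain = c("threatened", "all")) {
  domain <- match.arg(domain)
  if (interval_km * 1000 > max(grid$width, grid$height))
    stop("sampling interval exceeds the extent")
  v <- raster_values_masked(td)
  cand <- which(t(!is.na(v) & if (domain == "threatened") v > 0 else TRUE))
  if (length(cand) == 0) stop("no candidate cells to sample")
  ctr <- cell_centers(grid)  # row-major order matches t() above

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  perm <- sample(cand)

  min_d2 <- (interval_km * 1000)^2 * (1 - 1e-12)
  kept <- integer(0)
  kx <- ky <- numeric(0)
  for (c_ in perm) {
    x <- ctr[c_, 1]; y <- ctr[c_, 2]
    if (length(kept) == 0 || all((kx - x)^2 + (ky - y)^2 >= min_d2)) {
      kept <- c(kept, c_)
      kx <- c(kx, x); ky <- c(ky, y)
      if (length(kept) >= n_target) break
    }
  }
  i <- (kept - 1) %/% grid$ncol + 1
  j <- (kept - 1) %% grid$ncol + 1
  pick <- cbind(i, j)
  data.frame(x = kx, y = ky,
             TD = v[pick],
             N = raster_values_masked(densities$N)[pick],
             A = raster_values_masked(densities$A)[pick],
             T = raster_values_masked(densities$T)[pick])
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

pearson_with_p <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(c(r = NA_real_, p = NA_real_))
  n <- length(x)
  r <- stats::cor(x, y)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  c(r = r, p = 2 * stats::pt(-abs(tstat), df = n - 2))
}

#' Correlation report for the integration index
#'
#' Pearson correlations (with two-sided p-values from the exact t transform,
#' n - 2 df) of TD against each density component and between the components,
#' plus the two average correlation degrees: the index-component average
#' (mean of r(TD,N), r(TD,A), r(TD,T)) and the component-component average
#' (mean of r(N,A), r(N,T), r(A,T)). A zero-variance column renders its
#' pairs undefined (NA).
#'
#' @param samples data.frame from [sample_surfaces()].
#' @return List with `pairs` (data.frame: pair, r, p) and the two averages.
#' @export
correlation_report <- function(samples) {
  stopifnot(nrow(samples) >= 3)
  cols <- list(TD = samples$TD, N = samples$N, A = samples$A, T = samples$T)
  pair_names <- list(c("TD", "N"), c("TD", "A"), c("TD", "T"),
                     c("N", "A"), c("N", "T"), c("A", "T"))
  res <- t(vapply(pair_names, function(p)
    pearson_with_p(cols[[p[1]]], cols[[p[2]]]), c(r = 0, p = 0)))
  pairs <- data.frame(pair = vapply(pair_names, paste, "", collapse = "-"),
                      r = res[, "r"], p = res[, "p"],
                      stringsAsFactors = FALSE)
  list(pairs = pairs,
       avg_index_corr = mean(res[1:3, "r"]),
       avg_component_corr = mean(res[4:6, "r"]),
       n = nrow(samples))
}
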