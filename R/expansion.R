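# Human-expansion detection between two land-cover epochs and 8-connected
# patch extraction.

#' Globeland30-style class codes treated as human land
#' @export
HUMAN_CODES <- c(cropland = 10L, artificial = 80L)

#' Detect human-expansion pixels between two epochs
#'
#' A pixel is expansion when its later-epoch class is a human code (cropland
#' or artificial surface by default) and its earlier-epoch class is not *any*
#' human code, so internal conversions between human classes (for example
#' cropland to artificial surface) never count. Nodata in either epoch
#' propagates.
#'
#' @param t0,t1 Grid-aligned integer land-cover [ts_raster]s for the earlier
#'   and later epoch.
#' @param human_codes Integer class codes counted as human land.
#' @param quiet Suppress the pixel-count message.
#' @return Binary integer [ts_raster] (1 = expansion, nodata 255).
#' @export
detect_expansion <- function(t0, t1, human_codes = HUMAN_CODES, quiet = FALSE) {
  check_aligned(t0, t1, "epoch rasters")
  if (length(human_codes) == 0) stop("human_codes must be non-empty")
  if (!is.na(t0$nodata) && t0$nodata %in% human_codes ||
      !is.na(t1$nodata) && t1$nodata %in% human_codes)
    stop("nodata sentinel collides with a human class code")
  v0 <- raster_values_masked(t0)
  v1 <- raster_values_masked(t1)
  if (!any(v0 %in% human_codes | v1 %in% human_codes))
    warning("no human class code present in either epoch")
  m <- matrix(255L, nrow(v0), ncol(v0))
  ok <- !is.na(v0) & !is.na(v1)
  m[ok] <- as.integer(v1[ok] %in% human_codes & !(v0[ok] %in% human_codes))
  if (!quiet)
    message(sprintf("expansion pixels: %d of %d valid (%d masked)",
                    sum(m == 1L), sum(ok), sum(!ok)))
  ts_raster(m, x0 = t0$transform[["x0"]], y0 = t0$transform[["y0"]],
            px = t0$transform[["px"]], py = t0$transform[["py"]],
            nodata = 255, crs_tag = t0$crs_tag, integer_values = TRUE)
}

# 8-connected labeling of a binary matrix; returns integer label matrix with
# 0 background and dense ids 1..K ordered by first row-major pixel.
label_components_8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  ones <- which(mask == 1L)  # column-major linear indices
  if (length(ones) == 0) return(lab)
  rank <- integer(nr * nc); rank[ones] <- seq_along(ones)
  ri <- ((ones - 1L) %% nr) + 1L
  ci <- ((ones - 1L) %/% nr) + 1L
  edges <- integer(0)
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    nri <- ri + off[1]; nci <- ci + off[2]
    ok <- nri >= 1L & nri <= nr & nci <= nc
    nlin <- (nci - 1L) * nr + nri
    ok[ok] <- mask[nlin[ok]] == 1L
    if (any(ok))
      edges <- c(edges, rbind(rank[ones[ok]], rank[nlin[ok]]))
  }
  g <- igraph::make_graph(edges = edges, n = length(ones), directed = FALSE)
  memb <- igraph::components(g)$membership
  # dense ids in row-major first-appearance order
  rm_order <- order((ri - 1L) * nc + ci)
  new_id <- integer(max(memb))
  k <- 0L
  for (p in rm_order) {
    m <- memb[p]
    if (new_id[m] == 0L) { k <- k + 1L; new_id[m] <- k }
  }
  lab[ones] <- new_id[memb]
  lab
}

#' Extract 8-connected expansion patches
#'
#' Groups expansion pixels into patches under the 8-neighbourhood rule
#' (diagonal neighbours connect), computes per-patch pixel counts and areas
#' (pixel count x pixel area, exact), and optionally traces dissolved polygon
#' footprints whose topology matches the labeling.
#'
#' @param mask Binary [ts_raster] from [detect_expansion()].
#' @param footprints Trace polygon footprints per patch (slower).
#' @return A `ts_patchset`: `patches` (data.frame: id, pixel_count, area_km2),
#'   `label_raster` (integer [ts_raster], 0 background), and `footprints`
#'   (list of `ts_geom`, or NULL).
#' @export
extract_patches <- function(mask, footprints = TRUE) {
  v <- raster_values_masked(mask)
  bin <- matrix(0L, nrow(v), ncol(v))
  bin[!is.na(v) & v == 1] <- 1L
  lab <- label_components_8(bin)
  k <- max(lab)
  area_px <- pixel_area_km2(mask)
  counts <- if (k > 0) tabulate(lab[lab > 0L], nbins = k) else integer(0)
  patches <- data.frame(id = seq_len(k),
                        pixel_count = counts,
                        area_km2 = counts * area_px)
  fp <- NULL
  if (footprints && k > 0)
    fp <- lapply(seq_len(k), function(id)
      trace_footprint(lab == id, mask$transform))
  lr <- ts_raster(lab, x0 = mask$transform[["x0"]], y0 = mask$transform[["y0"]],
                  px = mask$transform[["px"]], py = mask$transform[["py"]],
                  nodata = NA, crs_tag = mask$crs_tag, integer_values = TRUE)
  structure(list(patches = patches, label_raster = lr, footprints = fp),
            class = "ts_patchset")
}

#' @export
print.ts_patchset <- function(x, ...) {
  cat(sprintf("<ts_patchset> %d patches, %d pixels, %.4f km2\n",
              nrow(x$patches), sum(x$patches$pixel_count),
              sum(x$patches$area_km2)))
  invisible(x)
}

# Trace the dissolved boundary of a pixel region as rings on the lattice,
# then map lattice coordinates to world coordinates. Rings that touch only
# at a corner stay separate (multipolygon), matching 8-connected labeling.
trace_footprint <- function(member, transform) {
  px_idx <- which(member, arr.ind = TRUE)
  nr <- nrow(member)
  inm <- function(i, j) {
    ok <- i >= 1 & i <= nr & j >= 1 & j <= ncol(member)
    res <- logical(length(i))
    res[ok] <- member[cbind(i[ok], j[ok])]
    res
  }
  i <- px_idx[, 1]; j <- px_idx[, 2]
  # directed lattice edges (x = j-1..j, y = i-1..i), interior kept on the
  # right while walking, one edge per exposed pixel side
  e <- list()
  add <- function(x1, y1, x2, y2, pix) {
    if (length(x1)) e[[length(e) + 1]] <<- cbind(x1, y1, x2, y2, pix)
  }
  n_abs <- !inm(i - 1L, j); s_abs <- !inm(i + 1L, j)
  w_abs <- !inm(i, j - 1L); e_abs <- !inm(i, j + 1L)
  pix <- seq_along(i)
  add(j[n_abs] - 1, i[n_abs] - 1, j[n_abs], i[n_abs] - 1, pix[n_abs])      # N: west->east
  add(j[e_abs], i[e_abs] - 1, j[e_abs], i[e_abs], pix[e_abs])              # E: north->south
  add(j[s_abs], i[s_abs], j[s_abs] - 1, i[s_abs], pix[s_abs])              # S: east->west
  add(j[w_abs] - 1, i[w_abs], j[w_abs] - 1, i[w_abs] - 1, pix[w_abs])      # W: south->north
  edges <- do.call(rbind, e)

  key <- function(x, y) x * (nr + 2) + y
  from_key <- key(edges[, 1], edges[, 2])
  ord <- order(from_key)
  edges <- edges[ord, , drop = FALSE]
  from_key <- from_key[ord]
  first <- match(unique(from_key), from_key)
  lookup_start <- stats::setNames(first, unique(from_key))
  used <- logical(nrow(edges))

  rings <- list()
  for (s in seq_len(nrow(edges))) {
    if (used[s]) next
    ring <- list()
    cur <- s
    repeat {
      used[cur] <- TRUE
      ring[[length(ring) + 1]] <- edges[cur, 1:2]
      nxt_key <- key(edges[cur, 3], edges[cur, 4])
      cand <- lookup_start[[as.character(nxt_key)]]
      if (is.null(cand) || is.na(cand)) stop("footprint tracing failed: open chain")
      cands <- cand
      while (cands[length(cands)] < nrow(edges) &&
             from_key[cands[length(cands)] + 1] == nxt_key)
        cands <- c(cands, cands[length(cands)] + 1)
      cands <- cands[!used[cands]]
      if (length(cands) == 0) break  # ring closed
      if (length(cands) > 1) {
        same <- cands[edges[cands, 5] == edges[cur, 5]]
        cands <- if (length(same)) same else cands
      }
      cur <- cands[1]
    }
    rings[[length(rings) + 1]] <- do.call(rbind, ring)
  }

  x0 <- transform[["x0"]]; y0 <- transform[["y0"]]
  pxs <- transform[["px"]]; pys <- transform[["py"]]
  rings <- lapply(rings, function(rg)
    cbind(x0 + rg[, 1] * pxs, y0 - rg[, 2] * pys))

  # assemble rings into polygons: negative world-signed-area rings are outers
  # under this tracing; assign each hole to the outer that contains it
  signed <- vapply(rings, ring_area_signed, 0)
  outers <- which(signed <= 0); holes <- which(signed > 0)
  polys <- lapply(outers, function(o) list(rings[[o]]))
  for (h in holes) {
    p <- rings[[h]][1, ]
    owner <- which(vapply(outers, function(o)
      point_in_ring(p[1] + 1e-9, p[2] - 1e-9, rings[[o]]), TRUE))[1]
    polys[[owner]] <- c(polys[[owner]], list(rings[[h]]))
  }
  structure(list(type = if (length(polys) > 1) "multipolygon" else "polygon",
                 polys = polys), class = "ts_geom")
}

#' Write a patch set to GeoJSON
#'
#' @param ps A `ts_patchset` with footprints.
#' @param path Output path.
#' @export
write_patches <- function(ps, path) {
  stopifnot(inherits(ps, "ts_patchset"))
  if (is.null(ps$footprints)) stop("patch set has no footprints")
  feats <- lapply(seq_len(nrow(ps$patches)), function(k)
    list(geometry = ps$footprints[[k]],
         attributes = list(id = ps$patches$id[k],
                           pixel_count = ps$patches$pixel_count[k],
                           area_km2 = ps$patches$area_km2[k])))
  write_vector(ts_vector(feats, crs_tag = ps$label_raster$crs_tag), path)
}
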