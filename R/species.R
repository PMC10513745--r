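# Threatened-species range handling: CR/EN/VU filtering, deduplication by
# binomial, and overlap counting against zones and expansion patches.

#' IUCN Red List categories counted as threatened
#' @export
THREATENED_CATEGORIES <- c("CR", "EN", "VU")

# severity order used when one binomial carries conflicting categories
.category_rank <- c(CR = 3L, EN = 2L, VU = 1L)

#' Species range set
#'
#' @param binomial Character vector of scientific names.
#' @param category IUCN category codes (CR/EN/VU/NT/LC/...).
#' @param range List of polygonal [ts_geom], one per record.
#' @param group Optional taxon group labels (bookkeeping only).
#' @return A `ts_species` object with one record per row.
#' @export
species_set <- function(binomial, category, range, group = NULL) {
  stopifnot(length(binomial) == length(category),
            length(binomial) == length(range))
  structure(list(binomial = as.character(binomial),
                 category = as.character(category),
                 range = range,
                 group = if (is.null(group)) rep(NA_character_, length(binomial))
                         else as.character(group),
                 deduplicated = FALSE),
            class = "ts_species")
}

#' @export
print.ts_species <- function(x, ...) {
  cat(sprintf("<ts_species> %d records, %d distinct binomials%s\n",
              length(x$binomial), length(unique(x$binomial)),
              if (x$deduplicated) " (threatened, deduplicated)" else ""))
  invisible(x)
}

#' @export
length.ts_species <- function(x) length(x$binomial)

#' Filter to threatened species and deduplicate by binomial
#'
#' Keeps CR, EN and VU records, then merges records sharing a binomial into
#' one species whose range is the union of the record geometries (kept as a
#' multi-part geometry; overlap tests treat parts with the even-odd rule).
#' When one binomial carries conflicting categories the most severe is kept
#' and the conflict is reported. Idempotent.
#'
#' @param sp A `ts_species`.
#' @param quiet Suppress the per-category log message.
#' @return A deduplicated `ts_species` containing only threatened species.
#' @export
filter_threatened <- function(sp, quiet = FALSE) {
  stopifnot(inherits(sp, "ts_species"))
  if (anyNA(sp$category))
    stop("records without a category attribute at indices: ",
         paste(which(is.na(sp$category)), collapse = ", "))
  keep <- sp$category %in% THREATENED_CATEGORIES
  bin <- sp$binomial[keep]; cat_ <- sp$category[keep]
  rng <- sp$range[keep]; grp <- sp$group[keep]
  ub <- unique(bin)
  out_cat <- character(length(ub)); out_rng <- vector("list", length(ub))
  out_grp <- character(length(ub))
  conflicts <- 0L
  for (k in seq_along(ub)) {
    idx <- which(bin == ub[k])
    cats <- unique(cat_[idx])
    if (length(cats) > 1) conflicts <- conflicts + 1L
    out_cat[k] <- cats[which.max(.category_rank[cats])]
    polys <- unlist(lapply(rng[idx], function(g) g$polys), recursive = FALSE)
    out_rng[[k]] <- structure(list(type = if (length(polys) > 1) "multipolygon"
                                          else "polygon",
                                   polys = polys), class = "ts_geom")
    out_grp[k] <- grp[idx][1]
  }
  if (!quiet)
    message(sprintf("threatened species: %d of %d records -> %d binomials (%s)%s",
                    sum(keep), length(sp$binomial), length(ub),
                    paste(names(table(out_cat)), table(out_cat),
                          sep = ":", collapse = " "),
                    if (conflicts) sprintf("; %d category conflicts resolved to most severe",
                                           conflicts) else ""))
  res <- species_set(ub, out_cat, out_rng, out_grp)
  res$deduplicated <- TRUE
  res
}

#' Count distinct species whose range overlaps a zone
#'
#' A species counts once when its (unioned) range intersects the zone with
#' positive area; ranges with convex parts are intersected exactly, so
#' enlarging a zone can never drop a species.
#'
#' @param sp A filtered `ts_species` (see [filter_threatened()]).
#' @param zone A polygonal [ts_geom].
#' @return Integer count.
#' @export
count_species_in_zone <- function(sp, zone) {
  stopifnot(inherits(sp, "ts_species"), is_polygonal(zone))
  sum(vapply(sp$range, function(rg) geoms_overlap(zone, rg), TRUE))
}

#' Count species involved in expansion patches within a cell
#'
#' A species is involved when its range overlaps the expansion footprint
#' inside the cell; overlap is resolved on the pixel grid (a species overlaps
#' when at least one expansion-pixel centre inside the cell falls in its
#' range), the same raster-overlay rule the density surfaces use.
#'
#' @param sp A filtered `ts_species`.
#' @param patches A `ts_patchset` from [extract_patches()].
#' @param cell_ring Ring matrix of the cell (e.g. from [rect_ring()]).
#' @return Integer count of distinct binomials.
#' @export
species_involved_in_patches <- function(sp, patches, cell_ring) {
  lab <- patches$label_raster
  v <- lab$values
  ones <- which(v > 0L)
  if (length(ones) == 0) return(0L)
  nr <- nrow(v)
  ctr <- pixel_centers(lab, rows = ((ones - 1L) %% nr) + 1L,
                       cols = ((ones - 1L) %/% nr) + 1L)
  inside <- point_in_ring(ctr[, 1], ctr[, 2], cell_ring)
  if (!any(inside)) return(0L)
  cx <- ctr[inside, 1]; cy <- ctr[inside, 2]
  sum(vapply(sp$range, function(rg) any(points_in_geom(cx, cy, rg)), TRUE))
}

#' Read a species range layer from GeoJSON
#'
#' Expects attributes `binomial` and `category` (optional `group`).
#' @param path GeoJSON path.
#' @return A `ts_species`.
#' @export
read_species <- function(path) {
  layer <- read_vector(path, geometry = "polygon")
  species_set(feature_attr(layer, "binomial"),
              feature_attr(layer, "category"),
              lapply(layer$features, function(f) f$geometry),
              group = feature_attr(layer, "group"))
}

#' Write a species range set to GeoJSON
#' @param sp A `ts_species`. @param path Output path.
#' @export
write_species <- function(sp, path) {
  feats <- lapply(seq_along(sp$binomial), function(k)
    list(geometry = sp$range[[k]],
         attributes = list(binomial = sp$binomial[k],
                           category = sp$category[k],
                           group = sp$group[k])))
  write_vector(ts_vector(feats), path)
}
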