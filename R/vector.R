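#' Vector layer of features
#'
#' A thin container for polygon (or point) features with attributes, read from
#' and written to GeoJSON. Coordinates live in the same planar equal-area
#' frame as the rasters (metres).
#'
#' @param features List of `list(geometry = <ts_geom>, attributes = <named list>)`.
#' @param crs_tag Frame identifier, as in [ts_raster()].
#' @return A `ts_vector` object.
#' @export
ts_vector <- function(features, crs_tag = "local-equal-area") {
  structure(list(features = features, crs_tag = crs_tag), class = "ts_vector")
}

#' @export
print.ts_vector <- function(x, ...) {
  types <- vapply(x$features, function(f) f$geometry$type, "")
  cat(sprintf("<ts_vector> %d features (%s), %s\n", length(x$features),
              paste(names(table(types)), table(types), collapse = ", "),
              x$crs_tag))
  invisible(x)
}

#' @export
length.ts_vector <- function(x) length(x$features)

#' Attribute column across all features
#' @param layer A `ts_vector`. @param name Attribute name.
#' @return Vector of values (`NA` where absent).
#' @export
feature_attr <- function(layer, name) {
  vals <- lapply(layer$features, function(f) {
    v <- f$attributes[[name]]
    if (is.null(v) || length(v) == 0) NA else v
  })
  unlist(vals, use.names = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

ring_to_coords <- function(ring) {
  closed <- rbind(ring, ring[1, ])
  lapply(seq_len(nrow(closed)), function(i) c(closed[i, 1], closed[i, 2]))
}

coords_to_ring <- function(coords) {
  m <- do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
  if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
  m
}

geom_to_geojson <- function(g) {
  if (g$type == "point")
    return(list(type = "Point", coordinates = as.list(g$coords)))
  polys <- lapply(g$polys, function(poly) lapply(poly, ring_to_coords))
  if (g$type == "polygon" && length(polys) == 1)
    list(type = "Polygon", coordinates = polys[[1]])
  else
    list(type = "MultiPolygon", coordinates = polys)
}

geojson_to_geom <- function(gj) {
  switch(gj$type,
    Point = ts_point(gj$coordinates[[1]], gj$coordinates[[2]]),
    Polygon = structure(list(type = "polygon",
                             polys = list(lapply(gj$coordinates, coords_to_ring))),
                        class = "ts_geom"),
    MultiPolygon = structure(list(type = "multipolygon",
                                  polys = lapply(gj$coordinates, function(poly)
                                    lapply(poly, coords_to_ring))),
                             class = "ts_geom"),
    stop("unsupported GeoJSON geometry type: ", gj$type))
}

#' Read a GeoJSON layer
#'
#' @param path Path to a GeoJSON FeatureCollection.
#' @param geometry `"polygon"` (default) rejects non-polygonal features,
#'   naming the offending feature indices; `"any"` keeps them (needed by the
#'   protected-area filter, which must *see* point features to drop them).
#' @param crs_tag Frame identifier to stamp on the layer.
#' @return A [ts_vector].
#' @export
read_vector <- function(path, geometry = c("polygon", "any"),
                        crs_tag = "local-equal-area") {
  geometry <- match.arg(geometry)
  if (!file.exists(path)) stop("vector file does not exist: ", path)
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection")
    stop("not a GeoJSON FeatureCollection: ", path)
  features <- lapply(gj$features, function(f)
    list(geometry = geojson_to_geom(f$geometry),
         attributes = f$properties %||% list()))
  if (geometry == "polygon") {
    bad <- which(!vapply(features, function(f) is_polygonal(f$geometry), TRUE))
    if (length(bad))
      stop("non-polygon features at indices: ", paste(bad, collapse = ", "))
  }
  if (!is.null(gj$crs_tag)) crs_tag <- gj$crs_tag
  ts_vector(features, crs_tag = crs_tag)
}

#' Write a layer to GeoJSON
#'
#' @param layer A [ts_vector]. @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vector <- function(layer, path) {
  stopifnot(inherits(layer, "ts_vector"))
  feats <- lapply(layer$features, function(f) {
    attrs <- f$attributes
    if (length(attrs) == 0) attrs <- structure(list(), names = character())
    list(type = "Feature",
         geometry = geom_to_geojson(f$geometry),
         properties = attrs)
  })
  doc <- list(type = "FeatureCollection", crs_tag = layer$crs_tag,
              features = feats)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = FALSE)
  invisible(path)
}
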