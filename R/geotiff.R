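# Minimal single-band GeoTIFF I/O in base R.
#
# Scope: uncompressed, single-sample-per-pixel, striped TIFF with the three
# georeferencing tags every GIS writes (ModelPixelScale, ModelTiepoint,
# GDAL_NODATA) plus a GeoKey citation carrying the frame tag. Float rasters
# are stored as Float64, integer rasters as Int32, so round-trips are exact.
# Both byte orders are accepted on read; files are written little-endian.

.tif_type_size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `11` = 4L, `12` = 8L)

.tif_read_vals <- function(buf, off, type, count, endian) {
  size <- .tif_type_size[[as.character(type)]]
  raw <- buf[(off + 1):(off + size * count)]
  switch(as.character(type),
    `1` = as.integer(raw),
    `2` = rawToChar(raw[raw != as.raw(0)]),
    `3` = readBin(raw, "integer", count, size = 2, signed = FALSE, endian = endian),
    `4` = readBin(raw, "integer", count, size = 4, endian = endian),
    `11` = readBin(raw, "double", count, size = 4, endian = endian),
    `12` = readBin(raw, "double", count, size = 8, endian = endian),
    stop("unsupported TIFF field type: ", type))
}

#' Read a single-band GeoTIFF
#'
#' Reads an uncompressed single-band GeoTIFF written by [write_raster()] or by
#' standard GIS software, restoring values, affine transform, nodata sentinel
#' and frame tag. Integer sample formats come back as integer rasters.
#'
#' @param path Path to a GeoTIFF file.
#' @return A [ts_raster].
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("raster file does not exist: ", path)
  buf <- readBin(path, "raw", file.size(path))
  if (length(buf) < 8) stop("not a TIFF file: ", path)
  order_tag <- rawToChar(buf[1:2])
  endian <- if (order_tag == "II") "little" else if (order_tag == "MM") "big" else
    stop("not a TIFF file (bad byte-order mark): ", path)
  magic <- readBin(buf[3:4], "integer", 1, size = 2, signed = FALSE, endian = endian)
  if (magic != 42L) stop("not a TIFF file (bad magic): ", path)
  ifd_off <- readBin(buf[5:8], "integer", 1, size = 4, endian = endian)

  n_entries <- readBin(buf[ifd_off + (1:2)], "integer", 1, size = 2,
                       signed = FALSE, endian = endian)
  tags <- list()
  for (k in seq_len(n_entries)) {
    e <- ifd_off + 2 + (k - 1) * 12
    tag <- readBin(buf[e + (1:2)], "integer", 1, size = 2, signed = FALSE, endian = endian)
    type <- readBin(buf[e + (3:4)], "integer", 1, size = 2, signed = FALSE, endian = endian)
    count <- readBin(buf[e + (5:8)], "integer", 1, size = 4, endian = endian)
    size <- .tif_type_size[[as.character(type)]]
    off <- if (size * count <= 4) e + 8 else
      readBin(buf[e + (9:12)], "integer", 1, size = 4, endian = endian)
    tags[[as.character(tag)]] <- .tif_read_vals(buf, off, type, count, endian)
  }

  need <- function(tag) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) stop(sprintf("TIFF tag %d missing in %s", tag, path))
    v
  }
  width <- need(256); height <- need(257)
  bits <- need(258)
  compression <- if (is.null(tags[["259"]])) 1L else tags[["259"]]
  if (compression != 1L) stop("compressed TIFF not supported: ", path)
  spp <- if (is.null(tags[["277"]])) 1L else tags[["277"]]
  if (spp != 1L) stop("multi-band TIFF not supported: ", path)
  fmt <- if (is.null(tags[["339"]])) 1L else tags[["339"]]
  strip_offs <- need(273)
  strip_counts <- need(279)

  scale <- tags[["33550"]]; tiepoint <- tags[["33922"]]
  if (is.null(scale) || is.null(tiepoint))
    stop("no georeference (ModelPixelScale/ModelTiepoint) in: ", path)

  data <- do.call(c, lapply(seq_along(strip_offs), function(i)
    buf[(strip_offs[i] + 1):(strip_offs[i] + strip_counts[i])]))
  n <- width * height
  vals <- switch(as.character(fmt),
    `1` = readBin(data, "integer", n, size = bits / 8,
                  signed = bits > 8, endian = endian),
    `2` = readBin(data, "integer", n, size = bits / 8, endian = endian),
    `3` = readBin(data, "double", n, size = bits / 8, endian = endian),
    stop("unsupported sample format ", fmt, " in: ", path))
  values <- matrix(vals, nrow = height, ncol = width, byrow = TRUE)

  nodata <- NA
  if (!is.null(tags[["42113"]])) nodata <- as.numeric(trimws(tags[["42113"]]))
  crs_tag <- "local-equal-area"
  if (!is.null(tags[["34737"]])) {
    crs_tag <- sub("\\|.*$", "", tags[["34737"]])
  }
  ts_raster(values,
            x0 = tiepoint[4], y0 = tiepoint[5], px = scale[1], py = scale[2],
            nodata = nodata, crs_tag = crs_tag,
            integer_values = fmt %in% c(1L, 2L))
}

.tif_pack <- function(x, size, endian = "little") {
  if (is.character(x)) return(c(charToRaw(x), as.raw(0)))
  writeBin(x, raw(), size = size, endian = endian)
}

#' Write a single-band GeoTIFF
#'
#' Integer rasters are stored as signed 32-bit integers, float rasters as
#' 64-bit IEEE doubles, so `read_raster(write_raster(r, p))` reproduces `r`
#' bit-for-bit. `NA` cells are written as the nodata sentinel when one is set.
#'
#' @param r A [ts_raster].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_raster <- function(r, path) {
  stopifnot(inherits(r, "ts_raster"))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir)
  v <- r$values
  if (anyNA(v)) {
    if (is.na(r$nodata)) {
      if (r$integer_values) stop("integer raster has NA cells but no nodata value")
      v[is.na(v)] <- NaN
    } else v[is.na(v)] <- r$nodata
  }
  height <- nrow(v); width <- ncol(v)
  tr <- r$transform

  if (r$integer_values) {
    bits <- 32L; fmt <- 2L
    payload <- writeBin(as.integer(t(v)), raw(), size = 4, endian = "little")
  } else {
    bits <- 64L; fmt <- 3L
    payload <- writeBin(as.double(t(v)), raw(), size = 8, endian = "little")
  }

  # GeoKeys: model type = projected, plus a citation carrying crs_tag
  citation <- c(charToRaw(paste0(r$crs_tag, "|")), as.raw(0))
  geokeys <- as.integer(c(1, 1, 0, 2,
                          1024, 0, 1, 1,
                          1026, 34737, length(citation), 0))

  entries <- list(
    list(256, 4L, 1L, as.integer(width)),
    list(257, 4L, 1L, as.integer(height)),
    list(258, 3L, 1L, as.integer(bits)),
    list(259, 3L, 1L, 1L),
    list(262, 3L, 1L, 1L),
    list(273, 4L, 1L, NA),          # strip offset, patched below
    list(277, 3L, 1L, 1L),
    list(278, 4L, 1L, as.integer(height)),
    list(279, 4L, 1L, length(payload)),
    list(339, 3L, 1L, fmt),
    list(33550, 12L, 3L, c(tr[["px"]], tr[["py"]], 0)),
    list(33922, 12L, 6L, c(0, 0, 0, tr[["x0"]], tr[["y0"]], 0)),
    list(34735, 3L, length(geokeys), geokeys),
    list(34737, 2L, length(citation), citation))
  if (!is.na(r$nodata)) {
    nd <- c(charToRaw(format(r$nodata, scientific = FALSE)), as.raw(0))
    entries <- c(entries, list(list(42113, 2L, length(nd), nd)))
  }
  entries <- entries[order(vapply(entries, `[[`, 0, 1))]

  serialize_val <- function(e) {
    type <- e[[2]]; val <- e[[4]]
    if (is.raw(val)) return(val)
    switch(as.character(type),
      `3` = writeBin(as.integer(val), raw(), size = 2, endian = "little"),
      `4` = writeBin(as.integer(val), raw(), size = 4, endian = "little"),
      `12` = writeBin(as.double(val), raw(), size = 8, endian = "little"))
  }

  n <- length(entries)
  ifd_off <- 8L
  ext_off <- ifd_off + 2L + 12L * n + 4L
  if (ext_off %% 2L == 1L) ext_off <- ext_off + 1L

  ext <- raw(0)
  entry_raw <- raw(0)
  for (e in entries) {
    tag <- e[[1]]; type <- e[[2]]; count <- e[[3]]
    bytes <- if (tag == 273) raw(4) else serialize_val(e)
    inline <- length(bytes) <= 4
    valfield <- if (inline) c(bytes, raw(4 - length(bytes))) else {
      off <- ext_off + length(ext)
      if (off %% 2L == 1L) { ext <- c(ext, raw(1)); off <- off + 1L }
      ext <- c(ext, bytes)
      writeBin(as.integer(off), raw(), size = 4, endian = "little")
    }
    entry_raw <- c(entry_raw,
                   writeBin(as.integer(tag), raw(), size = 2, endian = "little"),
                   writeBin(as.integer(type), raw(), size = 2, endian = "little"),
                   writeBin(as.integer(count), raw(), size = 4, endian = "little"),
                   valfield)
  }
  strip_off <- ext_off + length(ext)
  if (strip_off %% 2L == 1L) { ext <- c(ext, raw(1)); strip_off <- strip_off + 1L }

  # patch the StripOffsets value field now that the layout is known
  idx <- which(vapply(entries, `[[`, 0, 1) == 273)
  pos <- (idx - 1) * 12 + 8
  entry_raw[pos + (1:4)] <- writeBin(as.integer(strip_off), raw(),
                                     size = 4, endian = "little")

  header <- c(charToRaw("II"),
              writeBin(42L, raw(), size = 2, endian = "little"),
              writeBin(ifd_off, raw(), size = 4, endian = "little"))
  ifd <- c(writeBin(n, raw(), size = 2, endian = "little"),
           entry_raw,
           writeBin(0L, raw(), size = 4, endian = "little"))
  pad <- raw(ext_off - (ifd_off + length(ifd)))
  writeBin(c(header, ifd, pad, ext, payload), path)
  invisible(path)
}
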