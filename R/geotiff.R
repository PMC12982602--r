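# Minimal single-band GeoTIFF codec.
#
# The impact dataset's file contract is narrow: one uncompressed single-band
# raster per file, integer codes (or float32 for LAI layers), a nodata value,
# and georeferencing carried by the baseline GeoTIFF tags (ModelPixelScale,
# ModelTiepoint, a GeoKey directory naming the EPSG code) plus the GDAL nodata
# tag. This file implements exactly that profile: classic little-endian TIFF,
# one strip, no compression. Readers such as GDAL/QGIS open these files
# directly; the reader here accepts any uncompressed single-band classic TIFF
# written with the same conventions.

TIFF_TYPE_SIZES <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `11` = 4L, `12` = 8L)

.u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
.u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")
.f64 <- function(x) writeBin(as.numeric(x), raw(), size = 8, endian = "little")

# unsigned 32-bit read (R ints are signed; offsets here stay < 2^31)
.r32 <- function(con) readBin(con, "integer", 1, size = 4, endian = "little")
.r16 <- function(con) readBin(con, "integer", 1, size = 2, signed = FALSE, endian = "little")

#' Write a single-band GeoTIFF
#'
#' Writes an uncompressed, single-strip, little-endian GeoTIFF with
#' georeferencing tags (pixel scale, tiepoint, EPSG GeoKey) and an optional
#' GDAL-style nodata tag. Integer rasters are stored as unsigned 8-bit (codes
#' must lie in 0..255); continuous rasters as IEEE float32 with `NA` stored as
#' NaN.
#'
#' @param values Matrix (`grid$nrow` x `grid$ncol`).
#' @param path Output file path.
#' @param grid [lai_grid()] providing the affine transform and CRS.
#' @param type `"uint8"` for categorical codes, `"float32"` for continuous.
#' @param nodata Optional numeric nodata value recorded in the file.
#' @return `path`, invisibly.
#' @seealso [read_geotiff()]
#' @export
write_geotiff <- function(values, path, grid, type = c("uint8", "float32"),
                          nodata = NULL) {
  type <- match.arg(type)
  stopifnot(is.matrix(values), nrow(values) == grid$nrow, ncol(values) == grid$ncol)
  nr <- grid$nrow; nc <- grid$ncol
  v <- t(values)  # row-major pixel order
  if (type == "uint8") {
    iv <- as.integer(v)
    if (anyNA(iv) || any(iv < 0L | iv > 255L))
      stop("uint8 GeoTIFF requires integer codes in 0..255 with no NA")
    img <- as.raw(iv)
    bps <- 8L; sfmt <- 1L
  } else {
    dv <- as.numeric(v)
    dv[is.na(dv)] <- NaN
    img <- writeBin(dv, raw(), size = 4, endian = "little")
    bps <- 32L; sfmt <- 3L
  }
  if (length(img) %% 2L == 1L) img <- c(img, as.raw(0))  # keep offsets even

  geokeys <- c(1L, 1L, 0L, 3L,            # version, revision, minor, key count
               1024L, 0L, 1L, 1L,         # GTModelType = projected
               1025L, 0L, 1L, 1L,         # RasterType = PixelIsArea
               3072L, 0L, 1L, grid$crs_epsg)
  nodata_ascii <- if (!is.null(nodata)) {
    s <- charToRaw(format(nodata, scientific = FALSE))
    c(s, as.raw(0))
  } else NULL

  ent <- list(
    list(256L, 4L, 1L, nc),
    list(257L, 4L, 1L, nr),
    list(258L, 3L, 1L, bps),
    list(259L, 3L, 1L, 1L),          # no compression
    list(262L, 3L, 1L, 1L),          # BlackIsZero
    list(273L, 4L, 1L, 8L),          # single strip at fixed offset 8
    list(277L, 3L, 1L, 1L),
    list(278L, 4L, 1L, nr),
    list(279L, 4L, 1L, length(img)),
    list(339L, 3L, 1L, sfmt),
    list(33550L, 12L, 3L, c(grid$pixel_size, grid$pixel_size, 0)),
    list(33922L, 12L, 6L, c(0, 0, 0, grid$xmin, grid$ymax, 0)),
    list(34735L, 3L, length(geokeys), geokeys)
  )
  if (!is.null(nodata_ascii))
    ent <- c(ent, list(list(42113L, 2L, length(nodata_ascii), nodata_ascii)))

  ifd_off <- 8L + length(img)
  ifd_len <- 2L + 12L * length(ent) + 4L
  ext_off <- ifd_off + ifd_len
  ext <- raw(0)
  entry_raw <- raw(0)
  for (e in ent) {
    tag <- e[[1]]; typ <- e[[2]]; cnt <- e[[3]]; val <- e[[4]]
    vb <- switch(as.character(typ),
                 `2` = as.raw(val),
                 `3` = .u16(val),
                 `4` = .u32(val),
                 `12` = .f64(val))
    if (length(vb) <= 4L) {
      field <- c(vb, raw(4L - length(vb)))
    } else {
      if (length(ext) %% 2L == 1L) ext <- c(ext, as.raw(0))
      field <- .u32(ext_off + length(ext))
      ext <- c(ext, vb)
    }
    entry_raw <- c(entry_raw, .u16(tag), .u16(typ), .u32(cnt), field)
  }

  out <- c(charToRaw("II"), .u16(42L), .u32(ifd_off),
           img,
           .u16(length(ent)), entry_raw, .u32(0L),
           ext)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(out, con)
  invisible(path)
}

read_tag_values <- function(con, typ, cnt, field_raw, fsize) {
  size <- TIFF_TYPE_SIZES[[as.character(typ)]]
  nbytes <- size * cnt
  vraw <- if (nbytes <= 4L) {
    field_raw[seq_len(nbytes)]
  } else {
    off <- readBin(field_raw, "integer", 1, size = 4, endian = "little")
    seek(con, off)
    readBin(con, "raw", nbytes)
  }
  switch(as.character(typ),
         `1` = as.integer(vraw),
         `2` = vraw,
         `3` = readBin(vraw, "integer", cnt, size = 2, signed = FALSE, endian = "little"),
         `4` = readBin(vraw, "integer", cnt, size = 4, endian = "little"),
         `11` = readBin(vraw, "numeric", cnt, size = 4, endian = "little"),
         `12` = readBin(vraw, "numeric", cnt, size = 8, endian = "little"),
         stop("unsupported TIFF type ", typ))
}

#' Read a single-band GeoTIFF
#'
#' Reads uncompressed single-band classic TIFFs as written by
#' [write_geotiff()] (uint8 or float32, any strip layout), recovering the pixel
#' matrix, the grid georeferencing and the nodata value.
#'
#' @param path File path.
#' @return List with `values` (matrix; float32 NaN mapped back to `NA`),
#'   `grid` ([lai_grid()]) and `nodata` (numeric or `NULL`).
#' @export
read_geotiff <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 2)
  if (!identical(rawToChar(magic), "II"))
    stop("read_geotiff: only little-endian TIFF is supported")
  if (.r16(con) != 42L) stop("read_geotiff: not a classic TIFF file")
  ifd_off <- .r32(con)
  seek(con, ifd_off)
  n_ent <- .r16(con)
  ents <- vector("list", n_ent)
  for (i in seq_len(n_ent)) {
    ents[[i]] <- list(tag = .r16(con), typ = .r16(con), cnt = .r32(con),
                      field = readBin(con, "raw", 4))
  }
  tags <- vapply(ents, `[[`, 0L, "tag")
  get <- function(tag) {
    i <- match(tag, tags)
    if (is.na(i)) return(NULL)
    e <- ents[[i]]
    read_tag_values(con, e$typ, e$cnt, e$field)
  }
  nc <- get(256L); nr <- get(257L)
  bps <- get(258L) %||% 1L
  comp <- get(259L) %||% 1L
  if (comp != 1L) stop("read_geotiff: compressed TIFF is not supported")
  spp <- get(277L) %||% 1L
  if (spp != 1L) stop("read_geotiff: only single-band rasters are supported")
  offs <- get(273L); cnts <- get(279L)
  sfmt <- get(339L) %||% 1L
  raw_data <- raw(0)
  for (i in seq_along(offs)) {
    seek(con, offs[i])
    raw_data <- c(raw_data, readBin(con, "raw", cnts[i]))
  }
  npix <- as.numeric(nr) * nc
  vals <- if (sfmt == 3L && bps == 32L) {
    v <- readBin(raw_data, "numeric", npix, size = 4, endian = "little")
    v[is.nan(v)] <- NA_real_
    v
  } else if (sfmt %in% c(1L, 2L) && bps == 8L) {
    as.integer(raw_data[seq_len(npix)])
  } else if (sfmt %in% c(1L, 2L) && bps == 16L) {
    readBin(raw_data, "integer", npix, size = 2, signed = sfmt == 2L, endian = "little")
  } else stop("read_geotiff: unsupported sample format (", sfmt, "/", bps, " bit)")
  values <- t(matrix(vals, nrow = nc, ncol = nr))  # undo row-major order

  scale <- get(33550L); tie <- get(33922L); keys <- get(34735L)
  epsg <- 0L
  if (!is.null(keys) && length(keys) >= 4L) {
    nk <- keys[4L]
    for (k in seq_len(nk)) {
      kk <- keys[4L * k + 1:4]
      if (kk[1] == 3072L) epsg <- kk[4L]
    }
  }
  grid <- lai_grid(nr, nc,
                   xmin = if (!is.null(tie)) tie[4] else 0,
                   ymax = if (!is.null(tie)) tie[5] else nr * 500,
                   pixel_size = if (!is.null(scale)) scale[1] else 500,
                   crs_epsg = epsg)
  nodata <- NULL
  nd <- get(42113L)
  if (!is.null(nd)) {
    s <- rawToChar(nd[nd != as.raw(0)])
    nodata <- suppressWarnings(as.numeric(s))
  }
  list(values = values, grid = grid, nodata = nodata)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
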