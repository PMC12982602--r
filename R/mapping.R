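# Severity-coded drought-impact rasters and the dataset file convention.
#
# One file per (crop, degree, year): code 1/2/3 marks pixels impacted at the
# file's severity degree (drought-covered / drought-damaged / crop failure),
# 0 marks assessed crop pixels without impact at that degree, and 99 marks
# non-crop or invalid pixels (also the file's nodata value). Filenames follow
# {Crop}_{Degree}_{Year}.tif with Crop in {Autumn, Summer, ER} and Degree in
# {DC, DD, CF}.

CROP_FILE_PREFIX <- c(summer = "Summer", autumn = "Autumn", early_rice = "ER")

#' Classify a drought-impact raster for one crop, degree and year
#'
#' Applies each region's calibrated threshold and key window: a crop pixel is
#' flagged with the degree's code iff its window-mean LAI is at or below
#' `T`% of its baseline-year window mean. Non-crop pixels, pixels outside any
#' calibrated region and pixels with an invalid or non-positive baseline are
#' coded 99; assessed but unflagged crop pixels are coded 0.
#'
#' @param cube `lai_cube` (the same smoothed cube used for calibration).
#' @param mask `crop_mask`.
#' @param calib `calibration_result` from [calibrate_all()].
#' @param crop,degree,year The map to produce.
#' @return Object of class `impact_raster` (integer code matrix + metadata).
#' @export
classify <- function(cube, mask, calib, crop, degree, year) {
  stopifnot(degree %in% DEGREES, crop %in% CROPS)
  codes <- matrix(99L, cube$grid$nrow, cube$grid$ncol)
  code <- DEGREE_CODES[[degree]]
  for (rid in mask$region_ids) {
    cm <- crop_region_mask(mask, crop, rid)
    if (!any(cm)) next
    row <- calib[calib$region_id == rid & calib$crop == crop &
                   calib$degree == degree, ]
    if (!nrow(row))
      stop("classify: no calibration for region ", rid, ", crop ", crop,
           ", degree ", degree)
    tw <- time_window(row$window_start_doy, row$window_end_doy,
                      diff(cube$composite_doys[1:2]))
    actual <- window_mean(cube, tw, year, cm)
    base <- window_mean(cube, tw, row$baseline_year, cm)
    ok <- cm & is.finite(actual) & is.finite(base) & base > 0
    flag <- ok & actual <= (row$T_percent / 100) * base
    codes[ok] <- 0L
    codes[flag] <- code
  }
  structure(list(codes = codes, crop = crop, degree = degree,
                 year = as.integer(year), grid = cube$grid),
            class = "impact_raster")
}

#' @export
print.impact_raster <- function(x, ...) {
  tab <- table(x$codes)
  cat(sprintf("<impact_raster> %s %s %d on %s; codes: %s\n",
              x$crop, x$degree, x$year, format(x$grid),
              paste(names(tab), as.integer(tab), sep = "=", collapse = " ")))
  invisible(x)
}

#' Check (and optionally enforce) severity nesting
#'
#' With ordered thresholds (`T_CF <= T_DD <= T_DC`) the flagged pixel sets
#' nest: crop failure implies drought-damaged implies drought-covered.
#' Calibration does not enforce that ordering, so this reports the violating
#' pixels (flagged at a severer degree but not at a milder one, both degrees
#' assessed) and can promote the milder flags so that CF ⊆ DD ⊆ DC.
#'
#' @param dc,dd,cf `impact_raster`s for one crop and year.
#' @param enforce If `TRUE`, milder-degree rasters are promoted to restore
#'   nesting.
#' @return List with `violations` (total), `detail` (per pair) and the three
#'   rasters (promoted when `enforce = TRUE`).
#' @export
check_nesting <- function(dc, dd, cf, enforce = FALSE) {
  if (!grids_identical(dc$grid, dd$grid) || !grids_identical(dd$grid, cf$grid))
    stop("check_nesting: rasters are on different grids")
  if (dc$crop != dd$crop || dd$crop != cf$crop ||
      dc$year != dd$year || dd$year != cf$year)
    stop("check_nesting: rasters must share crop and year")
  v_cf_dd <- cf$codes == 3L & dd$codes == 0L
  v_cf_dc <- cf$codes == 3L & dc$codes == 0L
  v_dd_dc <- dd$codes == 2L & dc$codes == 0L
  detail <- c(cf_not_dd = sum(v_cf_dd), cf_not_dc = sum(v_cf_dc),
              dd_not_dc = sum(v_dd_dc))
  if (enforce) {
    dd$codes[v_cf_dd] <- 2L
    v_dd_dc <- dd$codes == 2L & dc$codes == 0L
    dc$codes[v_dd_dc] <- 1L
  }
  list(violations = sum(detail), detail = detail, dc = dc, dd = dd, cf = cf)
}

#' Write an impact raster in the dataset file convention
#'
#' GeoTIFF with an unsigned 8-bit band, nodata 99 and the grid's
#' georeferencing, named `{Crop}_{Degree}_{Year}.tif` (Autumn / Summer / ER).
#'
#' @param raster An `impact_raster`.
#' @param out_dir Output directory (created if needed).
#' @return The file path written.
#' @export
write_impact_tiff <- function(raster, out_dir) {
  stopifnot(inherits(raster, "impact_raster"))
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  fname <- sprintf("%s_%s_%d.tif", CROP_FILE_PREFIX[[raster$crop]],
                   raster$degree, raster$year)
  path <- file.path(out_dir, fname)
  write_geotiff(raster$codes, path, raster$grid, type = "uint8", nodata = 99)
  path
}

#' Read an impact raster written by [write_impact_tiff()]
#'
#' Crop, degree and year are recovered from the filename.
#'
#' @param path File path named `{Crop}_{Degree}_{Year}.tif`.
#' @return An `impact_raster`.
#' @export
read_impact_tiff <- function(path) {
  parts <- strsplit(sub("\\.tif$", "", basename(path)), "_")[[1]]
  if (length(parts) != 3L || !(parts[1] %in% CROP_FILE_PREFIX) ||
      !(parts[2] %in% DEGREES))
    stop("read_impact_tiff: filename does not follow {Crop}_{Degree}_{Year}.tif")
  g <- read_geotiff(path)
  structure(list(codes = matrix(as.integer(g$values), nrow(g$values)),
                 crop = names(CROP_FILE_PREFIX)[CROP_FILE_PREFIX == parts[1]],
                 degree = parts[2], year = as.integer(parts[3]),
                 grid = g$grid),
            class = "impact_raster")
}

#' Merge per-region impact rasters into one mosaic
#'
#' Regions occupy disjoint footprints on a shared grid; the mosaic takes each
#' raster's non-99 codes, leaves pixels outside every region at 99, and
#' errors if two rasters disagree on a pixel.
#'
#' @param rasters List of `impact_raster`s for one (crop, degree, year).
#' @return The mosaic `impact_raster`.
#' @export
merge_regions <- function(rasters) {
  stopifnot(length(rasters) >= 1L)
  base <- rasters[[1]]
  out <- matrix(99L, base$grid$nrow, base$grid$ncol)
  for (r in rasters) {
    if (!grids_identical(r$grid, base$grid))
      stop("merge_regions: rasters are on different grids")
    if (r$crop != base$crop || r$degree != base$degree || r$year != base$year)
      stop("merge_regions: rasters must share crop, degree and year")
    has <- r$codes != 99L
    clash <- has & out != 99L & out != r$codes
    if (any(clash))
      stop("merge_regions: overlapping pixels with non-identical codes")
    out[has] <- r$codes[has]
  }
  structure(list(codes = out, crop = base$crop, degree = base$degree,
                 year = base$year, grid = base$grid),
            class = "impact_raster")
}

#' Per-region impacted-area summary of an impact raster
#'
#' Counts flagged pixels per region and converts to thousand hectares; by
#' construction these totals equal [extracted_area()] for the same inputs.
#'
#' @param raster An `impact_raster`.
#' @param mask The `crop_mask` providing region labels.
#' @return Data frame with `region_id`, `crop`, `degree`, `year`,
#'   `area_thousand_ha`.
#' @export
impact_area_summary <- function(raster, mask) {
  code <- DEGREE_CODES[[raster$degree]]
  do.call(rbind, lapply(mask$region_ids, function(rid) {
    inreg <- !is.na(mask$region) & mask$region == rid
    data.frame(region_id = rid, crop = raster$crop, degree = raster$degree,
               year = raster$year,
               area_thousand_ha = sum(raster$codes[inreg] == code) *
                 pixel_area_kha(raster$grid))
  }))
}
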