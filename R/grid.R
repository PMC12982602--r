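#' Raster grid specification
#'
#' A light container for a regular north-up raster grid: dimensions, upper-left
#' corner, square pixel size and a projected CRS given by its EPSG code. All
#' rasters in a pipeline run share one grid, mirroring a single-tile 500 m
#' satellite-composite layout.
#'
#' @param nrow,ncol Grid dimensions in pixels.
#' @param xmin X coordinate of the left edge (map units, metres).
#' @param ymax Y coordinate of the top edge (map units, metres).
#' @param pixel_size Pixel edge length in metres (default 500).
#' @param crs_epsg Integer EPSG code of the projected CRS (metadata only; no
#'   reprojection is performed anywhere in the package).
#' @return An object of class `lai_grid`.
#' @export
lai_grid <- function(nrow, ncol, xmin = 0, ymax = nrow * pixel_size,
                     pixel_size = 500, crs_epsg = 32650L) {
  stopifnot(nrow >= 1, ncol >= 1, pixel_size > 0)
  structure(
    list(nrow = as.integer(nrow), ncol = as.integer(ncol),
         xmin = as.numeric(xmin), ymax = as.numeric(ymax),
         pixel_size = as.numeric(pixel_size), crs_epsg = as.integer(crs_epsg)),
    class = "lai_grid"
  )
}

#' @export
print.lai_grid <- function(x, ...) {
  cat(sprintf("<lai_grid> %d x %d px, %g m, origin (%g, %g), EPSG:%d\n",
              x$nrow, x$ncol, x$pixel_size, x$xmin, x$ymax, x$crs_epsg))
  invisible(x)
}

#' @export
format.lai_grid <- function(x, ...) {
  sprintf("%dx%d@%gm", x$nrow, x$ncol, x$pixel_size)
}

grids_identical <- function(a, b) {
  isTRUE(all.equal(unclass(a), unclass(b), tolerance = 1e-9))
}

#' Pixel-centre coordinates of a grid
#'
#' @param grid A [lai_grid()].
#' @return List with numeric vectors `x` (length ncol) and `y` (length nrow);
#'   `y` decreases from the top row down (north-up convention).
#' @export
grid_centers <- function(grid) {
  list(
    x = grid$xmin + (seq_len(grid$ncol) - 0.5) * grid$pixel_size,
    y = grid$ymax - (seq_len(grid$nrow) - 0.5) * grid$pixel_size
  )
}

#' Area of one pixel in thousand hectares
#'
#' A 500 m x 500 m pixel covers 25 ha = 0.025 thousand ha, the unit in which
#' historical drought statistics are published.
#'
#' @param grid A [lai_grid()].
#' @return Scalar, thousand hectares per pixel.
#' @export
pixel_area_kha <- function(grid) {
  (grid$pixel_size^2) / 1e4 / 1e3  # m^2 -> ha -> thousand ha
}

#' Nearest-neighbour alignment of a raster onto a target grid
#'
#' Each target pixel takes the value of the source pixel whose centre is
#' nearest to the target pixel centre. Values are copied, never interpolated,
#' so categorical rasters (crop masks, region labels) stay categorical. Both
#' grids must be in the same CRS; cross-CRS reprojection is out of scope.
#'
#' @param values Numeric or integer matrix on `src_grid` (`nrow` x `ncol`).
#' @param src_grid,target_grid [lai_grid()] objects sharing one EPSG code.
#' @return Matrix on `target_grid` dimensions.
#' @export
align_nearest <- function(values, src_grid, target_grid) {
  if (src_grid$crs_epsg != target_grid$crs_epsg)
    stop("align_nearest: source and target grids are in different CRSs (EPSG ",
         src_grid$crs_epsg, " vs ", target_grid$crs_epsg,
         "); reprojection is not supported")
  stopifnot(is.matrix(values),
            nrow(values) == src_grid$nrow, ncol(values) == src_grid$ncol)
  tc <- grid_centers(target_grid)
  # nearest source pixel index along each axis, clamped to the source extent
  col_idx <- round((tc$x - src_grid$xmin) / src_grid$pixel_size + 0.5)
  row_idx <- round((src_grid$ymax - tc$y) / src_grid$pixel_size + 0.5)
  col_idx <- pmin(pmax(col_idx, 1L), src_grid$ncol)
  row_idx <- pmin(pmax(row_idx, 1L), src_grid$nrow)
  values[row_idx, col_idx, drop = FALSE]
}
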