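# Candidate phenological time windows on the 8-day composite calendar.
#
# Candidate windows are all contiguous runs of composites inside a crop's
# growing season; they are computational search windows, not agronomic stages.
# The window whose calibrated threshold best matches the historical statistics
# becomes that crop's "key phenological period".

#' Composite calendar for one year
#'
#' Day-of-year start dates of the satellite composites, anchored at DOY 1
#' following the MODIS 8-day convention (1, 9, ..., 361; 46 composites per
#' year for an 8-day step). Leap day is ignored: DOY 366 never starts a
#' composite.
#'
#' @param step_days Composite length in days (default 8).
#' @return Integer vector of composite start DOYs.
#' @export
composite_calendar <- function(step_days = 8L) {
  stopifnot(step_days >= 1)
  seq.int(1L, 365L, by = as.integer(step_days))
}

#' Construct a time window
#'
#' A closed interval of composite start DOYs. Both endpoints must lie on the
#' composite calendar.
#'
#' @param start_doy,end_doy Inclusive DOY bounds, on the calendar.
#' @param step_days Composite step (default 8).
#' @return Object of class `time_window` with `start_doy`, `end_doy` and the
#'   composite DOYs it spans.
#' @export
time_window <- function(start_doy, end_doy, step_days = 8L) {
  cal <- composite_calendar(step_days)
  if (!(start_doy %in% cal) || !(end_doy %in% cal))
    stop("time_window: endpoints must lie on the composite calendar (step ",
         step_days, ")")
  if (start_doy > end_doy) stop("time_window: start_doy > end_doy")
  structure(list(start_doy = as.integer(start_doy),
                 end_doy = as.integer(end_doy),
                 doys = cal[cal >= start_doy & cal <= end_doy]),
            class = "time_window")
}

#' @export
format.time_window <- function(x, ...) {
  sprintf("DOY %d-%d (%d composites)", x$start_doy, x$end_doy, length(x$doys))
}

#' @export
print.time_window <- function(x, ...) {
  cat("<time_window>", format(x), "\n"); invisible(x)
}

#' Enumerate candidate time windows within a growing season
#'
#' All contiguous composite runs `[i, j]` with `i <= j` among the `m`
#' composites falling in `[doy_start, doy_end]`, giving `m(m+1)/2` candidates.
#' Season bounds that do not lie on the composite calendar are snapped
#' conservatively: the start up and the end down to the nearest composite DOY,
#' keeping every candidate inside the stated season. The span DOY 145-273 at an
#' 8-day step holds 17 composites and yields 153 candidate windows.
#'
#' @param doy_start,doy_end Growing-season bounds (inclusive).
#' @param step_days Composite step (default 8).
#' @return List of [time_window()] objects ordered by (start, end).
#' @export
enumerate_windows <- function(doy_start, doy_end, step_days = 8L) {
  stopifnot(doy_start <= doy_end)
  cal <- composite_calendar(step_days)
  doys <- cal[cal >= doy_start & cal <= doy_end]
  if (length(doys) == 0L)
    stop("enumerate_windows: no composite dates inside [", doy_start, ", ",
         doy_end, "]")
  out <- vector("list", length(doys) * (length(doys) + 1L) / 2L)
  k <- 0L
  for (i in seq_along(doys)) {
    for (j in i:length(doys)) {
      k <- k + 1L
      out[[k]] <- time_window(doys[i], doys[j], step_days)
    }
  }
  out
}

#' Per-pixel mean LAI over a time window
#'
#' Arithmetic mean of the valid LAI composites inside the window, for one year
#' and one crop mask. Non-crop pixels and pixels with no valid composite in
#' the window are `NA`.
#'
#' @param cube A `lai_cube` (see [generate_lai_cube()]).
#' @param window A [time_window()].
#' @param year Calendar year present in the cube.
#' @param crop_mask Logical matrix on the cube grid (`TRUE` = crop pixel), or
#'   `NULL` to average over every pixel.
#' @return Numeric matrix (`nrow` x `ncol`) of window means.
#' @export
window_mean <- function(cube, window, year, crop_mask = NULL) {
  yi <- match(year, cube$years)
  if (is.na(yi)) stop("window_mean: year ", year, " is not in the cube")
  ci <- match(window$doys, cube$composite_doys)
  if (anyNA(ci))
    stop("window_mean: window extends outside the cube's composite calendar")
  nr <- cube$grid$nrow; nc <- cube$grid$ncol
  npix <- nr * nc
  v <- matrix(cube$values[, , ci, yi, drop = FALSE], npix, length(ci))
  ok <- matrix(cube$valid[, , ci, yi, drop = FALSE], npix, length(ci))
  v[!ok] <- 0
  s <- rowSums(v)
  n <- rowSums(ok)
  m <- ifelse(n > 0L, s / n, NA_real_)
  if (!is.null(crop_mask)) {
    stopifnot(is.matrix(crop_mask), nrow(crop_mask) == nr, ncol(crop_mask) == nc)
    m[!as.vector(crop_mask)] <- NA_real_
  }
  matrix(m, nr, nc)
}
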