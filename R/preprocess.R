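# Pre-processing of the LAI cube: Savitzky-Golay smoothing of each pixel's
# yearly composite series, and fill-value masking.

sg_matrix <- function(n, len, polyorder) {
  # Linear smoothing operator (len x len) applying a Savitzky-Golay filter of
  # window n to a series of length len. Interior points use the centred
  # kernel; the first/last half-windows use the off-centre rows of the same
  # local least-squares fit, so polynomials of degree <= polyorder are
  # reproduced exactly along the whole series.
  H <- signal::sgolay(p = polyorder, n = n)
  H <- matrix(as.numeric(H), n, n)
  h <- (n - 1L) %/% 2L
  A <- matrix(0, len, len)
  for (t in seq_len(len)) {
    if (t <= h) {
      A[t, 1:n] <- H[t, ]
    } else if (t > len - h) {
      A[t, (len - n + 1L):len] <- H[n - (len - t), ]
    } else {
      A[t, (t - h):(t + h)] <- H[h + 1L, ]
    }
  }
  A
}

check_sg_params <- function(window_length, polyorder) {
  if (window_length %% 2L == 0L || window_length < 3L)
    stop("Savitzky-Golay window_length must be an odd integer >= 3")
  if (polyorder >= window_length) {
    warning("polyorder ", polyorder, " >= window_length ", window_length,
            "; clamping to ", window_length - 1L, call. = FALSE)
    polyorder <- window_length - 1L
  }
  as.integer(polyorder)
}

#' Savitzky-Golay smoothing of one series
#'
#' Local least-squares polynomial smoothing. Each point is replaced by the
#' value at its position of a degree-`polyorder` polynomial fitted to the
#' surrounding `window_length` points; the first and last half-windows use the
#' off-centre evaluations of the edge windows, so series length is preserved
#' and polynomials of degree `<= polyorder` pass through unchanged.
#'
#' A `polyorder >= window_length` is over-parameterised; it is clamped to
#' `window_length - 1` with a warning. Note the 3-point window with (clamped)
#' quadratic order reproduces every input exactly — the default configuration
#' is deliberately light smoothing.
#'
#' @param series Numeric vector, length `>= window_length`.
#' @param window_length Odd integer `>= 3` (default 3).
#' @param polyorder Polynomial degree (default 3, clamped to 2 for the default
#'   window).
#' @return Smoothed numeric vector of the same length.
#' @export
sg_smooth <- function(series, window_length = 3L, polyorder = 3L) {
  polyorder <- check_sg_params(window_length, polyorder)
  if (length(series) < window_length)
    stop("series length ", length(series), " is shorter than window_length ",
         window_length)
  A <- sg_matrix(as.integer(window_length), length(series), polyorder)
  as.numeric(A %*% series)
}

#' Mark fill values in a cube invalid
#'
#' Entries equal to any of the sentinel `fill_values` have their validity flag
#' cleared; they are skipped by smoothing and window means, and a pixel with no
#' valid composite inside a window is excluded from extraction (coded 99 in the
#' output rasters). Valid values are never altered.
#'
#' @param cube A `lai_cube`.
#' @param fill_values Numeric vector of sentinel codes (e.g. 249:255 style
#'   MODIS fills).
#' @return The cube with an updated validity mask.
#' @export
mask_invalid <- function(cube, fill_values) {
  stopifnot(inherits(cube, "lai_cube"))
  if (length(fill_values)) {
    bad <- array(cube$values %in% fill_values, dim = dim(cube$values))
    cube$valid <- cube$valid & !bad
  }
  cube
}

#' Smooth every pixel's yearly LAI series
#'
#' Applies [sg_smooth()] per pixel per year over that year's composite series
#' (never across year boundaries). Invalid composites are linearly
#' interpolated from the valid neighbours before filtering and remain flagged
#' invalid afterwards; smoothed values are floored at 0 (LAI is non-negative).
#'
#' @param cube A `lai_cube`.
#' @param window_length,polyorder Filter parameters as in [sg_smooth()].
#' @return The cube with smoothed values, marked `smoothed = TRUE`.
#' @export
smooth_cube <- function(cube, window_length = 3L, polyorder = 3L) {
  stopifnot(inherits(cube, "lai_cube"))
  polyorder <- check_sg_params(window_length, polyorder)
  ncomp <- length(cube$composite_doys)
  if (ncomp < window_length)
    stop("cube has fewer composites (", ncomp, ") than window_length")
  A <- sg_matrix(as.integer(window_length), ncomp, polyorder)
  npix <- cube$grid$nrow * cube$grid$ncol
  for (yi in seq_along(cube$years)) {
    X <- t(matrix(cube$values[, , , yi], npix, ncomp))    # ncomp x npix
    ok <- t(matrix(cube$valid[, , , yi], npix, ncomp))
    if (!all(ok)) {
      gap_cols <- which(colSums(!ok) > 0L & colSums(ok) >= 2L)
      for (j in gap_cols) {
        v <- which(ok[, j])
        X[!ok[, j], j] <- stats::approx(v, X[v, j], xout = which(!ok[, j]),
                                        rule = 2)$y
      }
    }
    Y <- A %*% X
    Y[Y < 0] <- 0
    cube$values[, , , yi] <- array(t(Y), c(cube$grid$nrow, cube$grid$ncol, ncomp))
  }
  cube$smoothed <- TRUE
  cube
}
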