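# Calibration of relative LAI thresholds and key phenological windows against
# annual historical drought-area statistics.
#
# For one region, every candidate (time window, threshold) pair yields an
# estimated annual drought-area series EA: pixels whose window-mean LAI falls
# at or below T% of the baseline-year window mean are counted and converted
# to thousand hectares, summed over the region's crops, plus the historical
# baseline-year area. Candidates are scored against the historical series HA
# by RMSE and Pearson R. By default one key phenological window is selected
# per crop (scored by the degree-pooled normalized RMSE) with a separate
# threshold per severity degree inside that window; per-degree windows are
# available as an option.

#' Select the baseline year of a region
#'
#' The year with the weakest drought impacts across all three severity
#' degrees, measured as the smallest sum of the three degree areas; ties go to
#' the earlier year. This year's LAI state serves as the no-drought reference.
#'
#' @param stats A `historical_stats` data frame.
#' @param region Region label.
#' @return Calendar year (integer).
#' @export
select_baseline_year <- function(stats, region) {
  s <- stats[stats$region_id == region, ]
  if (!nrow(s)) stop("no statistics for region ", region)
  ndeg <- stats::aggregate(degree ~ year, s, function(d) length(unique(d)))
  if (any(ndeg$degree < 3L))
    stop("region ", region, ": incomplete degree series (need DC, DD and CF ",
         "for every year)")
  tot <- stats::aggregate(area_thousand_ha ~ year, s, sum)
  yrs <- sort(tot$year)
  tot <- tot[match(yrs, tot$year), ]
  yrs[which.min(tot$area_thousand_ha)]
}

#' Drought-impacted area extracted under a relative threshold
#'
#' Counts valid crop pixels whose actual window-mean LAI is at or below
#' `T`% of the baseline-year window mean and converts the count to thousand
#' hectares (25 ha per 500 m pixel). Pixels with missing or non-positive
#' baseline are excluded entirely — a zero baseline would flag bare ground at
#' any threshold.
#'
#' @param actual,baseline Window-mean matrices from [window_mean()], on the
#'   same pixel set (`NA` marks non-crop/invalid pixels).
#' @param T Threshold percentage in `[0, 100]`.
#' @param grid The [lai_grid()] the matrices live on.
#' @return Area in thousand hectares.
#' @export
extracted_area <- function(actual, baseline, T, grid) {
  if (!identical(dim(actual), dim(baseline)))
    stop("extracted_area: actual and baseline are on different pixel sets")
  stopifnot(T >= 0, T <= 100)
  ok <- is.finite(actual) & is.finite(baseline) & baseline > 0
  n <- sum(actual[ok] <= (T / 100) * baseline[ok])
  n * pixel_area_kha(grid)
}

#' Estimated annual drought-area series
#'
#' Sums the per-crop extracted areas year by year and adds the historical
#' baseline-year area `HA_base`, giving the estimated series EA compared
#' against the historical series during calibration.
#'
#' @param components Named list, crop -> numeric vector of extracted areas
#'   with years as names; all crops must cover the same years.
#' @param HA_base Historical area of the baseline year (thousand ha).
#' @return Named numeric vector EA by year.
#' @export
estimated_series <- function(components, HA_base) {
  stopifnot(length(components) >= 1L, HA_base >= 0)
  yrs <- names(components[[1]])
  for (cmp in components) {
    if (is.null(names(cmp)) || !identical(sort(names(cmp)), sort(yrs)))
      stop("estimated_series: crops cover different year sets")
  }
  ea <- Reduce(`+`, lapply(components, function(cmp) cmp[yrs]))
  ea + HA_base
}

#' Pearson correlation between estimated and historical series
#'
#' Standard product-moment correlation. If either series has zero variance the
#' correlation is undefined and `NA` is returned; such candidates are skipped
#' during calibration.
#'
#' @param EA,HA Numeric vectors of equal length `>= 3`.
#' @return Correlation in `[-1, 1]`, or `NA` if undefined.
#' @export
pearson_r <- function(EA, HA) {
  if (length(EA) != length(HA)) stop("pearson_r: length mismatch")
  if (length(EA) < 3L) stop("pearson_r: need at least 3 points")
  ea <- EA - mean(EA); ha <- HA - mean(HA)
  den <- sqrt(sum(ea^2)) * sqrt(sum(ha^2))
  if (den == 0) return(NA_real_)
  sum(ea * ha) / den
}

#' Root-mean-square error between estimated and historical series
#'
#' @param EA,HA Numeric vectors of equal length `>= 1`.
#' @return RMSE in the units of the inputs (thousand ha).
#' @export
rmse <- function(EA, HA) {
  if (length(EA) != length(HA)) stop("rmse: length mismatch")
  if (!length(EA)) stop("rmse: empty series")
  sqrt(mean((EA - HA)^2))
}

# --- internal machinery for the grid search -------------------------------

# Per-pixel window means for every candidate window and year, for the pixels
# of one (region, crop). Returns a list of npix x nyear matrices.
window_mean_stack <- function(cube, pix, windows) {
  nr <- cube$grid$nrow; nc <- cube$grid$ncol
  npix_all <- nr * nc
  ncomp <- length(cube$composite_doys)
  ny <- length(cube$years)
  v <- matrix(cube$values, npix_all, ncomp * ny)[pix, , drop = FALSE]
  ok <- matrix(cube$valid, npix_all, ncomp * ny)[pix, , drop = FALSE]
  v[!ok] <- 0
  dim(v) <- c(length(pix), ncomp, ny)
  dim(ok) <- c(length(pix), ncomp, ny)
  # prefix sums along the composite axis for O(1) window sums
  cs <- apply(v, c(1, 3), cumsum)   # ncomp x npix x ny
  cn <- apply(ok, c(1, 3), cumsum)
  lapply(windows, function(w) {
    ci <- match(w$doys, cube$composite_doys)
    i1 <- ci[1]; i2 <- ci[length(ci)]
    s <- cs[i2, , ] - (if (i1 > 1) cs[i1 - 1L, , ] else 0)
    n <- cn[i2, , ] - (if (i1 > 1) cn[i1 - 1L, , ] else 0)
    A <- ifelse(n > 0, s / n, NA_real_)
    matrix(A, length(pix), ny)
  })
}

# Critical threshold-grid index per pixel/year: the smallest index i such that
# actual <= (Tg[i]/100) * baseline, or nT+1 if no grid threshold flags the
# pixel. Semantics match extracted_area()'s direct comparison exactly
# (findInterval locates the index, then one-step fix-ups resolve floating-
# point rounding of the division).
critical_index <- function(A, B, Tg) {
  nT <- length(Tg)
  bad <- !is.finite(A) | !is.finite(B) | B <= 0
  r <- 100 * A / B
  r[bad] <- Inf
  pos <- findInterval(r, Tg) + 1L
  pos[pos > nT + 1L] <- nT + 1L
  for (rep in 1:2) {
    can_dec <- which(!bad & pos > 1L &
                       A <= (Tg[pmax(pos - 1L, 1L)] / 100) * B)
    pos[can_dec] <- pos[can_dec] - 1L
    can_inc <- which(!bad & pos <= nT &
                       !(A <= (Tg[pmin(pos, nT)] / 100) * B))
    pos[can_inc] <- pos[can_inc] + 1L
  }
  pos[bad] <- nT + 1L
  pos
}

# counts matrix (nT x nyear): counts[i, y] = number of pixels flagged at
# threshold Tg[i] in year y
count_by_threshold <- function(pos, nT) {
  ny <- ncol(pos)
  out <- matrix(0L, nT, ny)
  for (y in seq_len(ny)) {
    tab <- tabulate(pos[, y], nbins = nT + 1L)
    out[, y] <- cumsum(tab)[seq_len(nT)]
  }
  out
}

# R and RMSE for every threshold of one window: EA_mat is nT x ny.
score_candidates <- function(EA_mat, HA) {
  ec <- EA_mat - rowMeans(EA_mat)
  hc <- HA - mean(HA)
  ssE <- rowSums(ec^2)
  den <- sqrt(ssE * sum(hc^2))
  R <- as.numeric(ec %*% hc) / den
  R[ssE == 0] <- NA_real_
  RMSE <- sqrt(rowMeans((EA_mat - matrix(HA, nrow(EA_mat), length(HA),
                                         byrow = TRUE))^2))
  list(R = R, RMSE = RMSE)
}

# Lexicographic comparison of candidate fits under a selection rule.
# rmse_r: min RMSE, then max R, then smaller T; r_rmse: max R, then min RMSE,
# then smaller T. Returns TRUE when a is strictly better than b.
better_fit <- function(a, b, selection) {
  if (is.null(b)) return(TRUE)
  if (selection == "rmse_r") {
    if (a$RMSE != b$RMSE) return(a$RMSE < b$RMSE)
    if (a$R != b$R) return(a$R > b$R)
  } else {
    if (a$R != b$R) return(a$R > b$R)
    if (a$RMSE != b$RMSE) return(a$RMSE < b$RMSE)
  }
  a$T < b$T
}

# Best threshold of one window under a selection rule; NULL when every
# candidate has undefined R (zero-variance EA).
pick_threshold <- function(sc, Tg, selection) {
  ok <- which(!is.na(sc$R))
  if (!length(ok)) return(NULL)
  if (selection == "rmse_r") {
    ok <- ok[sc$RMSE[ok] == min(sc$RMSE[ok])]
    ok <- ok[sc$R[ok] == max(sc$R[ok])]
  } else {
    ok <- ok[sc$R[ok] == max(sc$R[ok])]
    ok <- ok[sc$RMSE[ok] == min(sc$RMSE[ok])]
  }
  i <- ok[1L]  # thresholds ascend: first = smallest T
  list(R = sc$R[i], RMSE = sc$RMSE[i], T = Tg[i], ti = i)
}

# Exact joint optimisation of two crops' thresholds for ONE window pair and
# one degree, with the other crops' contribution fixed. Returns the best cell
# under the selection rule. M* are nT x ny area matrices (counts * pixel
# area); fixed already includes HA_base.
optimize_cell_pair <- function(Ma, Mb, fixed, HA, selection) {
  ny <- length(HA)
  C <- fixed - HA
  # squared-error surface: ssq(Ta, Tb) = A2[Ta] + B2[Tb] + sum(C^2)
  #   + 2 (Ma C)[Ta] + 2 (Mb C)[Tb] + 2 (Ma Mb')[Ta, Tb]
  A2 <- rowSums(Ma^2) + 2 * as.numeric(Ma %*% C)
  B2 <- rowSums(Mb^2) + 2 * as.numeric(Mb %*% C)
  G <- Ma %*% t(Mb)
  ssq <- outer(A2, B2, `+`) + sum(C^2) + 2 * G
  ssq[ssq < 0] <- 0  # guard fp round-off on exact fits
  # Pearson R surface from centred pieces
  hc <- HA - mean(HA)
  ssH <- sum(hc^2)
  Mac <- Ma - rowMeans(Ma); Mbc <- Mb - rowMeans(Mb)
  fc <- fixed - mean(fixed)
  num <- outer(as.numeric(Mac %*% hc) + sum(fc * hc),
               as.numeric(Mbc %*% hc), `+`)
  den2 <- outer(rowSums(Mac^2) + 2 * as.numeric(Mac %*% fc),
                rowSums(Mbc^2) + 2 * as.numeric(Mbc %*% fc), `+`) +
    sum(fc^2) + 2 * (Mac %*% t(Mbc))
  R <- num / sqrt(den2 * ssH)
  R[den2 <= 0] <- NA_real_
  if (all(is.na(R))) return(NULL)
  RMSE <- sqrt(ssq / ny)
  RMSE[is.na(R)] <- NA_real_
  if (selection == "rmse_r") {
    m1 <- min(RMSE, na.rm = TRUE)
    cells <- which(RMSE == m1)
    m2 <- max(R[cells])
    cells <- cells[R[cells] == m2]
  } else {
    m2 <- max(R, na.rm = TRUE)
    cells <- which(R == m2)
    m1 <- min(RMSE[cells])
    cells <- cells[RMSE[cells] == m1]
  }
  nTa <- nrow(Ma)
  ta <- (cells - 1L) %% nTa + 1L
  tb <- (cells - 1L) %/% nTa + 1L
  o <- order(ta, tb)[1L]  # smaller first-crop T, then second
  list(R = if (selection == "rmse_r") R[cells[o]] else m2,
       RMSE = if (selection == "rmse_r") m1 else RMSE[cells[o]],
       tia = ta[o], tib = tb[o])
}

# pooled window score across degrees: sum of RMSE / sd(HA_degree)
pooled_score <- function(fits, HA_sd) {
  sum(vapply(seq_along(fits), function(i) fits[[i]]$RMSE / HA_sd[i], 0))
}

#' Calibrate thresholds and key windows for one region
#'
#' Runs the grid search over candidate time windows and the discrete
#' threshold grid for all three severity degrees of one region.
#'
#' Window scope: with `window_scope = "per_crop"` (default) one key
#' phenological window is selected per crop — scored by the degree-pooled
#' normalized RMSE (each degree's best-threshold RMSE divided by the standard
#' deviation of its historical series, summed) — and each degree gets its own
#' threshold inside that window. With `"per_degree"` every degree selects its
#' own window independently.
#'
#' Selection rule: `"rmse_r"` (default) ranks candidates by lowest RMSE, ties
#' by highest Pearson R, then smaller threshold, then earlier/shorter window;
#' `"r_rmse"` ranks by highest R first. On noise-free data both rules agree
#' (the truth candidate has R = 1 and RMSE = 0); under noise RMSE anchors the
#' threshold magnitude, which the affine-invariant R cannot.
#'
#' Multi-crop regions use block coordinate descent over crop pairs: all crops
#' start at T = 100 with the full-season window, each block move jointly and
#' exactly optimises one pair's assignments with the remaining crops held
#' fixed, iterating until stable (at most `max_iter` rounds). For a two-crop
#' region the single block move is the exact joint search.
#'
#' @param cube `lai_cube` (smooth it first; calibration and statistics must
#'   see the same values).
#' @param mask `crop_mask`.
#' @param stats `historical_stats` covering every cube year for the region.
#' @param region Region label.
#' @param windows_per_crop Named list, crop -> list of [time_window()]
#'   candidates (e.g. from [enumerate_windows()]).
#' @param baseline_year Baseline year (e.g. from [select_baseline_year()]).
#' @param thresholds Increasing numeric threshold grid (default `0:100`).
#' @param window_scope `"per_crop"` or `"per_degree"`.
#' @param selection `"rmse_r"` or `"r_rmse"`.
#' @param max_iter Coordinate-descent iteration cap.
#' @param degrees Severity degrees to calibrate (default all three).
#' @return List with one entry per degree: `crops` (per crop: `T`, `window`),
#'   `R`, `RMSE`, `EA`, `HA` (named by year), plus `baseline_year`,
#'   `iterations`, `converged`.
#' @export
calibrate_region <- function(cube, mask, stats, region, windows_per_crop,
                             baseline_year, thresholds = 0:100,
                             window_scope = c("per_crop", "per_degree"),
                             selection = c("rmse_r", "r_rmse"),
                             max_iter = 10L, degrees = DEGREES) {
  window_scope <- match.arg(window_scope)
  selection <- match.arg(selection)
  stopifnot(inherits(cube, "lai_cube"), inherits(mask, "crop_mask"),
            all(degrees %in% DEGREES), length(degrees) >= 1L)
  Tg <- as.numeric(thresholds)
  if (is.unsorted(Tg, strictly = TRUE)) stop("thresholds must be increasing")
  nT <- length(Tg)
  years <- cube$years
  ny <- length(years)
  bl_yi <- match(baseline_year, years)
  if (is.na(bl_yi)) stop("baseline year ", baseline_year, " not in the cube")
  ap <- pixel_area_kha(cube$grid)

  HA <- list(); HA_sd <- numeric(length(degrees))
  for (di in seq_along(degrees)) {
    s <- stats[stats$region_id == region & stats$degree == degrees[di], ]
    h <- s$area_thousand_ha[match(years, s$year)]
    if (anyNA(h))
      stop("historical statistics for region ", region, ", degree ",
           degrees[di], " do not cover every cube year")
    if (stats::var(h) == 0)
      stop("historical series for region ", region, ", degree ", degrees[di],
           " has zero variance; Pearson R is undefined for every candidate")
    HA[[di]] <- h
    HA_sd[di] <- stats::sd(h)
  }
  HA_base <- vapply(HA, `[`, 0, bl_yi)

  crops <- intersect(CROPS, names(windows_per_crop))
  if (!length(crops)) stop("windows_per_crop names no known crop")

  # per crop: area matrices (nT x ny, thousand ha) for every candidate window
  crop_data <- list()
  for (cr in crops) {
    wins <- windows_per_crop[[cr]]
    pix <- which(crop_region_mask(mask, cr, region))
    if (!length(pix)) stop("region ", region, " has no pixels of crop ", cr)
    A_list <- window_mean_stack(cube, pix, wins)
    areas <- lapply(A_list, function(A) {
      B <- A[, bl_yi]
      pos <- critical_index(A, matrix(B, nrow(A), ny), Tg)
      count_by_threshold(matrix(pos, nrow(A), ny), nT) * ap
    })
    starts <- vapply(wins, `[[`, 0L, "start_doy")
    ends <- vapply(wins, `[[`, 0L, "end_doy")
    full_i <- which(starts == min(starts) & ends == max(ends))[1]
    crop_data[[cr]] <- list(windows = wins, areas = areas, full_i = full_i)
  }

  no_candidate <- function() {
    stop("calibration failed for region ", region,
         ": every candidate has an undefined Pearson R ",
         "(zero-variance estimated series)")
  }
  # state: per crop, shared window index + per-degree threshold indices
  state <- lapply(crop_data, function(cd)
    list(wi = cd$full_i, ti = rep(nT, length(degrees))))
  crop_area <- function(cr, di) {
    st <- state[[cr]]
    crop_data[[cr]]$areas[[st$wi]][st$ti[di], ]
  }

  iter <- 0L; converged <- FALSE
  if (length(crops) == 1L) {
    cr <- crops[1L]
    cd <- crop_data[[cr]]
    if (window_scope == "per_degree") {
      # independent exhaustive search per degree
      for (di in seq_along(degrees)) {
        sel <- NULL; sel_wi <- NA_integer_
        for (wi in seq_along(cd$windows)) {
          sc <- score_candidates(cd$areas[[wi]] + HA_base[di], HA[[di]])
          pk <- pick_threshold(sc, Tg, selection)
          if (!is.null(pk) && better_fit(pk, sel, selection)) {
            sel <- pk; sel_wi <- wi
          }
        }
        if (is.null(sel)) no_candidate()
        state[[cr]]$ti[di] <- sel$ti
        # per-degree windows are stored per degree via a parallel slot
        state[[cr]]$wi_deg[di] <- sel_wi
      }
      state[[cr]]$wi <- state[[cr]]$wi_deg[1]
    } else {
      # one window per crop: pooled normalized RMSE across degrees
      best <- NULL
      for (wi in seq_along(cd$windows)) {
        fits <- vector("list", length(degrees))
        okw <- TRUE
        for (di in seq_along(degrees)) {
          sc <- score_candidates(cd$areas[[wi]] + HA_base[di], HA[[di]])
          pk <- pick_threshold(sc, Tg, selection)
          if (is.null(pk)) { okw <- FALSE; break }
          fits[[di]] <- pk
        }
        if (!okw) next
        cand <- list(wi = wi, fits = fits,
                     score = pooled_score(fits, HA_sd))
        if (is.null(best) || cand$score < best$score) best <- cand
      }
      if (is.null(best)) no_candidate()
      state[[cr]]$wi <- best$wi
      state[[cr]]$ti <- vapply(best$fits, `[[`, 0L, "ti")
    }
    iter <- 1L; converged <- TRUE
  } else if (window_scope == "per_crop") {
    pairs <- utils::combn(crops, 2L, simplify = FALSE)
    while (iter < max_iter && !converged) {
      iter <- iter + 1L
      changed <- FALSE
      for (pr in pairs) {
        cda <- crop_data[[pr[1]]]; cdb <- crop_data[[pr[2]]]
        fixed <- lapply(seq_along(degrees), function(di) {
          f <- rep(HA_base[di], ny)
          for (other in setdiff(crops, pr)) f <- f + crop_area(other, di)
          f
        })
        best <- NULL
        for (wa in seq_along(cda$windows)) {
          Ma <- cda$areas[[wa]]
          for (wb in seq_along(cdb$windows)) {
            Mb <- cdb$areas[[wb]]
            fits <- vector("list", length(degrees))
            okw <- TRUE
            for (di in seq_along(degrees)) {
              cell <- optimize_cell_pair(Ma, Mb, fixed[[di]], HA[[di]],
                                         selection)
              if (is.null(cell)) { okw <- FALSE; break }
              fits[[di]] <- cell
            }
            if (!okw) next
            cand <- list(wa = wa, wb = wb, fits = fits,
                         score = pooled_score(fits, HA_sd))
            if (is.null(best) || cand$score < best$score) best <- cand
          }
        }
        if (is.null(best)) no_candidate()
        new_a <- list(wi = best$wa,
                      ti = vapply(best$fits, `[[`, 0L, "tia"))
        new_b <- list(wi = best$wb,
                      ti = vapply(best$fits, `[[`, 0L, "tib"))
        if (!identical(new_a, state[[pr[1]]]) ||
            !identical(new_b, state[[pr[2]]])) {
          state[[pr[1]]] <- new_a
          state[[pr[2]]] <- new_b
          changed <- TRUE
        }
      }
      if (!changed) converged <- TRUE
    }
  } else {
    # multi-crop, per-degree windows: independent block descent per degree
    pairs <- utils::combn(crops, 2L, simplify = FALSE)
    for (cr in crops) state[[cr]]$wi_deg <- rep(crop_data[[cr]]$full_i,
                                                length(degrees))
    converged <- TRUE
    for (di in seq_along(degrees)) {
      st <- lapply(crop_data, function(cd) list(wi = cd$full_i, ti = nT))
      it <- 0L; conv <- FALSE
      while (it < max_iter && !conv) {
        it <- it + 1L
        changed <- FALSE
        for (pr in pairs) {
          f <- rep(HA_base[di], ny)
          for (other in setdiff(crops, pr))
            f <- f +
              crop_data[[other]]$areas[[st[[other]]$wi]][st[[other]]$ti, ]
          best <- NULL
          for (wa in seq_along(crop_data[[pr[1]]]$windows)) {
            Ma <- crop_data[[pr[1]]]$areas[[wa]]
            for (wb in seq_along(crop_data[[pr[2]]]$windows)) {
              cell <- optimize_cell_pair(Ma, crop_data[[pr[2]]]$areas[[wb]],
                                         f, HA[[di]], selection)
              if (is.null(cell)) next
              cand <- list(R = cell$R, RMSE = cell$RMSE, T = Tg[cell$tia],
                           wa = wa, wb = wb, cell = cell)
              if (better_fit(cand, best, selection)) best <- cand
            }
          }
          if (is.null(best)) no_candidate()
          na <- list(wi = best$wa, ti = best$cell$tia)
          nb <- list(wi = best$wb, ti = best$cell$tib)
          if (!identical(na, st[[pr[1]]]) || !identical(nb, st[[pr[2]]])) {
            st[[pr[1]]] <- na
            st[[pr[2]]] <- nb
            changed <- TRUE
          }
        }
        if (!changed) conv <- TRUE
      }
      for (cr in crops) {
        state[[cr]]$wi_deg[di] <- st[[cr]]$wi
        state[[cr]]$ti[di] <- st[[cr]]$ti
      }
      iter <- max(iter, it)
      converged <- converged && conv
    }
  }

  # assemble per-degree results from the final state
  out <- list()
  for (di in seq_along(degrees)) {
    EA <- rep(HA_base[di], ny)
    res_crops <- list()
    for (cr in crops) {
      st <- state[[cr]]
      wi <- if (!is.null(st$wi_deg)) st$wi_deg[di] else st$wi
      EA <- EA + crop_data[[cr]]$areas[[wi]][st$ti[di], ]
      res_crops[[cr]] <- list(crop = cr, T = Tg[st$ti[di]],
                              window = crop_data[[cr]]$windows[[wi]])
    }
    EA <- stats::setNames(as.numeric(EA), years)
    out[[degrees[di]]] <- list(
      region_id = region, degree = degrees[di], crops = res_crops,
      R = pearson_r(EA, HA[[di]]), RMSE = rmse(EA, HA[[di]]),
      EA = EA, HA = stats::setNames(HA[[di]], years),
      baseline_year = baseline_year, iterations = iter, converged = converged)
  }
  out
}

#' Calibrate one severity degree of one region
#'
#' Convenience wrapper around [calibrate_region()] with per-degree window
#' scope, returning the single degree's fit.
#'
#' @inheritParams calibrate_region
#' @param degree One of `"DC"`, `"DD"`, `"CF"`.
#' @return One degree's entry of [calibrate_region()]'s result.
#' @export
calibrate_degree <- function(cube, mask, stats, region, degree,
                             windows_per_crop, baseline_year,
                             thresholds = 0:100,
                             selection = c("rmse_r", "r_rmse"),
                             max_iter = 10L) {
  stopifnot(degree %in% DEGREES)
  selection <- match.arg(selection)
  calibrate_region(cube, mask, stats, region, windows_per_crop,
                   baseline_year, thresholds, window_scope = "per_degree",
                   selection = selection, max_iter = max_iter,
                   degrees = degree)[[degree]]
}

#' Calibrate all regions, crops and severity degrees
#'
#' Driver over [calibrate_region()]: enumerates candidate windows from each
#' region's growing seasons and auto-selects baseline years from the
#' statistics unless overridden.
#'
#' @param cube `lai_cube` (smoothed).
#' @param mask `crop_mask`.
#' @param stats `historical_stats`.
#' @param growing_seasons Named list, region -> named list, crop ->
#'   `c(doy_start, doy_end)`.
#' @param baseline_years Optional named vector region -> year; defaults to
#'   [select_baseline_year()] per region.
#' @param thresholds Threshold grid (default `0:100`).
#' @param window_scope,selection See [calibrate_region()].
#' @param step_days Composite step used for window enumeration (default: the
#'   cube's).
#' @return A `calibration_result`: data frame with one row per (region, crop,
#'   degree) holding `T_percent`, `window_start_doy`, `window_end_doy`, `R`,
#'   `RMSE`, `baseline_year`, plus an `ea_series` attribute with the per
#'   (region, degree, year) EA and HA values.
#' @export
calibrate_all <- function(cube, mask, stats, growing_seasons,
                          baseline_years = NULL, thresholds = 0:100,
                          window_scope = c("per_crop", "per_degree"),
                          selection = c("rmse_r", "r_rmse"),
                          step_days = NULL) {
  window_scope <- match.arg(window_scope)
  selection <- match.arg(selection)
  if (is.null(step_days))
    step_days <- diff(cube$composite_doys[1:2])
  rows <- list(); series <- list()
  for (rid in names(growing_seasons)) {
    wpc <- lapply(growing_seasons[[rid]], function(gs)
      enumerate_windows(gs[1], gs[2], step_days))
    bl <- if (!is.null(baseline_years) && rid %in% names(baseline_years))
      baseline_years[[rid]] else select_baseline_year(stats, rid)
    fits <- calibrate_region(cube, mask, stats, rid, wpc, bl, thresholds,
                             window_scope = window_scope,
                             selection = selection)
    for (deg in DEGREES) {
      fit <- fits[[deg]]
      for (cr in names(fit$crops)) {
        fc <- fit$crops[[cr]]
        rows[[length(rows) + 1L]] <- data.frame(
          region_id = rid, crop = cr, degree = deg, T_percent = fc$T,
          window_start_doy = fc$window$start_doy,
          window_end_doy = fc$window$end_doy,
          R = fit$R, RMSE = fit$RMSE, baseline_year = bl)
      }
      series[[length(series) + 1L]] <- data.frame(
        region_id = rid, degree = deg, year = as.integer(names(fit$EA)),
        EA = as.numeric(fit$EA), HA = as.numeric(fit$HA))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "ea_series") <- do.call(rbind, series)
  class(out) <- c("calibration_result", "data.frame")
  out
}
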