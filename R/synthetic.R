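# Synthetic satellite-composite scenes with known ground truth.
#
# The generator emulates the inputs of the drought-impact pipeline: a 500 m
# LAI cube on the 8-day composite calendar, per-crop coverage masks, a region
# partition, and annual historical drought-area statistics per severity
# degree. Every scene embeds known truth thresholds and key windows, so the
# calibration stage can be tested as a parameter-recovery experiment.

CROPS <- c("summer", "autumn", "early_rice")
DEGREES <- c("DC", "DD", "CF")
DEGREE_CODES <- c(DC = 1L, DD = 2L, CF = 3L)

#' Declare one synthetic region
#'
#' A region is a rectangular block of the grid with its own crops, growing
#' seasons, truth thresholds/windows, baseline year and drought-event
#' calendar.
#'
#' @param region_id Character label.
#' @param row_range,col_range Integer length-2 inclusive pixel ranges.
#' @param crops Subset of `c("summer", "autumn", "early_rice")`.
#' @param growing_season Named list, crop -> `c(doy_start, doy_end)` in
#'   `[1, 365]`.
#' @param truth_thresholds Named list, crop -> named vector
#'   `c(DC = , DD = , CF = )` of percentages in `[0, 100]`, non-increasing
#'   from DC to CF (severer impacts require deeper LAI depressions).
#' @param truth_windows Named list, crop -> [time_window()] inside the growing
#'   season; drought events depress the LAI composites inside this window.
#' @param baseline_year Year simulated with no drought events.
#' @param drought_events Data frame with columns `year`, `crop`, `fraction`
#'   (of the region's crop pixels affected, in `[0, 1]`) and `depression`
#'   (mean LAI depression factor in `[0, 1)`).
#' @param crop_fraction Fraction of the region's pixels carrying each crop
#'   (default 1; crop pixels are a seeded random subset when < 1).
#' @return Object of class `region_spec`.
#' @export
region_spec <- function(region_id, row_range, col_range, crops,
                        growing_season, truth_thresholds, truth_windows,
                        baseline_year, drought_events, crop_fraction = 1) {
  stopifnot(length(row_range) == 2L, length(col_range) == 2L,
            row_range[1] <= row_range[2], col_range[1] <= col_range[2],
            all(crops %in% CROPS), length(crops) >= 1L)
  for (cr in crops) {
    gs <- growing_season[[cr]]
    if (is.null(gs) || gs[1] >= gs[2] || gs[1] < 1 || gs[2] > 365)
      stop("region ", region_id, ": growing season for ", cr,
           " must satisfy 1 <= doy_start < doy_end <= 365")
    tt <- truth_thresholds[[cr]]
    if (is.null(tt) || !all(DEGREES %in% names(tt)))
      stop("region ", region_id, ": truth thresholds for ", cr,
           " must name DC, DD and CF")
    if (any(tt < 0 | tt > 100) || tt["DC"] < tt["DD"] || tt["DD"] < tt["CF"])
      stop("region ", region_id, ": truth thresholds must lie in [0,100] ",
           "and decrease from DC to DD to CF")
    tw <- truth_windows[[cr]]
    if (is.null(tw) || !inherits(tw, "time_window") ||
        tw$start_doy < gs[1] || tw$end_doy > gs[2])
      stop("region ", region_id, ": truth window for ", cr,
           " must be a time_window inside the growing season")
  }
  ev <- as.data.frame(drought_events)
  if (nrow(ev)) {
    stopifnot(all(c("year", "crop", "fraction", "depression") %in% names(ev)))
    if (!all(ev$crop %in% crops))
      stop("region ", region_id, ": drought event references a crop the ",
           "region does not grow")
    if (any(ev$fraction < 0 | ev$fraction > 1))
      stop("region ", region_id, ": event fraction must lie in [0, 1]")
    if (any(ev$depression < 0 | ev$depression >= 1))
      stop("region ", region_id, ": event depression must lie in [0, 1)")
    if (any(ev$year == baseline_year))
      stop("region ", region_id, ": the baseline year must stay event-free")
  }
  structure(list(region_id = region_id, row_range = as.integer(row_range),
                 col_range = as.integer(col_range), crops = crops,
                 growing_season = growing_season,
                 truth_thresholds = truth_thresholds,
                 truth_windows = truth_windows,
                 baseline_year = as.integer(baseline_year),
                 drought_events = ev, crop_fraction = crop_fraction),
            class = "region_spec")
}

#' Simulation configuration
#'
#' Scene-level knobs for the synthetic generator. The per-pixel LAI curve is a
#' raised-cosine bell over each crop's growing season with a per-pixel random
#' amplitude (spatial heterogeneity the relative-threshold method is designed
#' to absorb), optional per-composite Gaussian noise, drought events that
#' depress the composites inside the crop's truth window, and multiplicative
#' lognormal noise on the derived statistics.
#'
#' @param seed Integer RNG seed; all scene randomness derives from it.
#' @param grid [lai_grid()] for the scene (default 500 m pixels).
#' @param years Strictly increasing calendar years.
#' @param regions List of [region_spec()] objects with disjoint footprints.
#' @param composite_step_days Composite length in days (default 8; must give
#'   at least two composites per year).
#' @param noise_sd Per-composite Gaussian LAI noise, standard deviation in LAI
#'   units (>= 0).
#' @param stats_noise_cv Coefficient of variation of the lognormal noise on
#'   derived statistics (>= 0; 0 means exact statistics).
#' @param amplitude_range Range of the per-pixel seasonal LAI amplitude.
#' @param background_lai Constant out-of-season/bare LAI level.
#' @param depression_spread Relative half-width of the per-pixel depression
#'   around an event's mean depression (`d * (1 + U(-spread, spread))`,
#'   clipped to `[0, 0.99]`). 0 gives every affected pixel exactly the event's
#'   depression; positive values spread pixel ratios into a continuum.
#' @param event_profile_sd Log-scale SD of the per-pixel temporal depression
#'   profile across the composites of the truth window. 0 depresses every
#'   composite by the same factor; positive values vary drought onset/shape
#'   from pixel to pixel while the window-mean LAI is still scaled by exactly
#'   `(1 - depression)`.
#' @param phenology_shift_days Half-width (days) of the per-pixel uniform
#'   jitter of the seasonal curve's timing, emulating spatially varying
#'   sowing/green-up dates. Drawn once per pixel and kept across years.
#' @param annual_amplitude_cv CV of a mean-one lognormal factor multiplying
#'   each pixel's seasonal curve independently every year — the ordinary
#'   inter-annual LAI variability (weather, management, non-drought stress)
#'   real composites show on top of drought signals. 0 makes every
#'   event-free year identical to the baseline.
#' @param fill_fraction Fraction of cube entries overwritten with
#'   `fill_value` to emulate failed retrievals (mask with [mask_invalid()]).
#' @param fill_value Sentinel value used for fills (default 255).
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(seed, grid, years, regions,
                              composite_step_days = 8L, noise_sd = 0,
                              stats_noise_cv = 0,
                              amplitude_range = c(1.5, 6.5),
                              background_lai = 0.05,
                              depression_spread = 0,
                              event_profile_sd = 0,
                              phenology_shift_days = 0,
                              annual_amplitude_cv = 0,
                              fill_fraction = 0, fill_value = 255) {
  stopifnot(inherits(grid, "lai_grid"), length(years) >= 1L,
            noise_sd >= 0, stats_noise_cv >= 0,
            depression_spread >= 0, depression_spread < 1,
            event_profile_sd >= 0, phenology_shift_days >= 0,
            annual_amplitude_cv >= 0,
            fill_fraction >= 0, fill_fraction < 1,
            length(amplitude_range) == 2L, amplitude_range[1] > 0)
  if (is.unsorted(years, strictly = TRUE))
    stop("years must be strictly increasing")
  if (length(composite_calendar(composite_step_days)) < 2L)
    stop("composite_step_days must give at least 2 composites per year")
  occ <- matrix(FALSE, grid$nrow, grid$ncol)
  for (rg in regions) {
    stopifnot(inherits(rg, "region_spec"))
    if (rg$row_range[2] > grid$nrow || rg$col_range[2] > grid$ncol)
      stop("region ", rg$region_id, " extends beyond the grid")
    blk <- occ[rg$row_range[1]:rg$row_range[2], rg$col_range[1]:rg$col_range[2]]
    if (any(blk))
      stop("regions overlap: pixel assigned to more than one region label")
    occ[rg$row_range[1]:rg$row_range[2], rg$col_range[1]:rg$col_range[2]] <- TRUE
    if (!all(rg$drought_events$year %in% years) && nrow(rg$drought_events))
      stop("region ", rg$region_id, ": drought event references a year ",
           "outside the simulated period")
    if (!(rg$baseline_year %in% years))
      stop("region ", rg$region_id, ": baseline year not in simulated years")
  }
  structure(list(seed = as.integer(seed), grid = grid,
                 years = as.integer(years), regions = regions,
                 composite_step_days = as.integer(composite_step_days),
                 noise_sd = noise_sd, stats_noise_cv = stats_noise_cv,
                 amplitude_range = amplitude_range,
                 background_lai = background_lai,
                 depression_spread = depression_spread,
                 event_profile_sd = event_profile_sd,
                 phenology_shift_days = phenology_shift_days,
                 annual_amplitude_cv = annual_amplitude_cv,
                 fill_fraction = fill_fraction, fill_value = fill_value),
            class = "simulation_config")
}

raised_cosine <- function(doys, season) {
  # unit-amplitude bell over [start, end], zero outside
  x <- (doys - season[1]) / (season[2] - season[1])
  ifelse(x >= 0 & x <= 1, sin(pi * x)^2, 0)
}

#' Generate a synthetic LAI cube, crop masks and ground truth
#'
#' Builds the full scene from a [simulation_config()]: deterministic given the
#' seed (two calls with the same config are bit-identical). Each crop pixel's
#' seasonal curve keeps the same amplitude in every year, so with
#' `noise_sd = 0` and no drought events every year reproduces the baseline
#' exactly; a drought event multiplies the composites inside the crop's truth
#' window by `(1 - depression)` for the stated fraction of the region's crop
#' pixels.
#'
#' @param config A [simulation_config()].
#' @return List with components `cube` (class `lai_cube`), `mask` (class
#'   `crop_mask`) and `truth` (class `synthetic_truth`; thresholds, windows,
#'   baseline years and the noise-free true impacted-area table).
#' @export
generate_lai_cube <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  g <- config$grid
  nr <- g$nrow; nc <- g$ncol; npix <- nr * nc
  doys <- composite_calendar(config$composite_step_days)
  ncomp <- length(doys)
  years <- config$years
  ny <- length(years)

  region_lab <- matrix(NA_character_, nr, nc)
  masks <- stats::setNames(
    lapply(CROPS, function(cr) matrix(FALSE, nr, nc)), CROPS)
  base_curve <- array(config$background_lai, c(nr, nc, ncomp))

  for (rg in config$regions) {
    rr <- rg$row_range[1]:rg$row_range[2]
    cc <- rg$col_range[1]:rg$col_range[2]
    region_lab[rr, cc] <- rg$region_id
    blk_idx <- which(!is.na(region_lab) & region_lab == rg$region_id)
    for (cr in rg$crops) {
      cf <- if (length(rg$crop_fraction) > 1L) rg$crop_fraction[[cr]]
            else rg$crop_fraction
      pix <- blk_idx
      if (cf < 1) {
        n_keep <- round(cf * length(blk_idx))
        pix <- sort(sample(blk_idx, n_keep))
      }
      mk <- masks[[cr]]
      mk[pix] <- TRUE
      masks[[cr]] <- mk
      amp <- stats::runif(length(pix), config$amplitude_range[1],
                          config$amplitude_range[2])
      shift <- if (config$phenology_shift_days > 0)
        stats::runif(length(pix), -config$phenology_shift_days,
                     config$phenology_shift_days)
      else rep(0, length(pix))
      gs <- rg$growing_season[[cr]]
      # per-pixel seasonal curve: amplitude and timing both vary spatially
      bells <- outer(shift, doys, function(s, t)
        raised_cosine(t - s, gs))
      for (t in seq_len(ncomp)) {
        if (!any(bells[, t] > 0)) next
        sl <- base_curve[, , t]
        sl[pix] <- sl[pix] + amp * bells[, t]
        base_curve[, , t] <- sl
      }
    }
  }

  values <- array(0, c(nr, nc, ncomp, ny))
  amp_sdlog <- sqrt(log(1 + config$annual_amplitude_cv^2))
  for (yi in seq_len(ny)) {
    yr_curve <- if (config$annual_amplitude_cv > 0) {
      m <- stats::rlnorm(npix, meanlog = -amp_sdlog^2 / 2, sdlog = amp_sdlog)
      base_curve * m  # recycles pixel-wise over composites
    } else base_curve
    noise <- if (config$noise_sd > 0)
      array(stats::rnorm(npix * ncomp, 0, config$noise_sd), c(nr, nc, ncomp))
    else 0
    values[, , , yi] <- pmax(yr_curve + noise, 0)
  }

  for (rg in config$regions) {
    ev <- rg$drought_events
    for (k in seq_len(nrow(ev))) {
      cr <- ev$crop[k]
      yi <- match(ev$year[k], years)
      crop_pix <- which(masks[[cr]] & !is.na(region_lab) &
                          region_lab == rg$region_id)
      n_aff <- round(ev$fraction[k] * length(crop_pix))
      aff <- sort(sample(crop_pix, n_aff))
      d <- ev$depression[k]
      if (config$depression_spread > 0) {
        d <- d * (1 + stats::runif(n_aff, -config$depression_spread,
                                   config$depression_spread))
        d <- pmin(pmax(d, 0), 0.99)
      } else d <- rep(d, n_aff)
      ci <- match(rg$truth_windows[[cr]]$doys, doys)
      # Per-pixel temporal depression profile g (weighted mean 1 under the
      # pixel's composite values), so the window-mean LAI is scaled by exactly
      # (1 - d) while the composite-level response pattern varies from pixel
      # to pixel, as drought onset and duration do in real scenes.
      k <- length(ci)
      yr_slab <- values[, , , yi]
      dim(yr_slab) <- c(nr * nc, ncomp)
      V <- yr_slab[aff, ci, drop = FALSE]
      if (config$event_profile_sd > 0 && k > 1L) {
        U <- matrix(exp(stats::rnorm(n_aff * k, 0, config$event_profile_sd)),
                    n_aff, k)
        vs <- rowSums(V)
        prof <- U * ifelse(vs > 0, vs / rowSums(V * U), 1)
        # shrink towards the uniform profile where needed so 1 - d*prof stays
        # in [0, 1]; the affine map preserves the weighted-mean constraint
        excess <- (prof - 1) * d
        alpha <- pmin(1, (1 - d) / apply(pmax(excess, 1e-12), 1, max))
        prof <- 1 + alpha * (prof - 1)
        fac <- 1 - d * prof
      } else {
        fac <- matrix(1 - d, n_aff, k)
      }
      for (j in seq_len(k)) {
        sl <- values[, , ci[j], yi]
        sl[aff] <- sl[aff] * fac[, j]
        values[, , ci[j], yi] <- sl
      }
    }
  }

  valid <- array(TRUE, c(nr, nc, ncomp, ny))
  if (config$fill_fraction > 0) {
    n_fill <- round(config$fill_fraction * length(values))
    at <- sample.int(length(values), n_fill)
    values[at] <- config$fill_value
  }

  cube <- structure(list(values = values, valid = valid,
                         composite_doys = doys, years = years, grid = g,
                         smoothed = FALSE),
                    class = "lai_cube")
  mask <- structure(list(masks = masks, region = region_lab,
                         region_ids = vapply(config$regions, `[[`, "", "region_id"),
                         grid = g),
                    class = "crop_mask")

  thr <- do.call(rbind, lapply(config$regions, function(rg) {
    do.call(rbind, lapply(rg$crops, function(cr) {
      data.frame(region_id = rg$region_id, crop = cr, degree = DEGREES,
                 T_percent = as.numeric(rg$truth_thresholds[[cr]][DEGREES]))
    }))
  }))
  win <- do.call(rbind, lapply(config$regions, function(rg) {
    do.call(rbind, lapply(rg$crops, function(cr) {
      tw <- rg$truth_windows[[cr]]
      data.frame(region_id = rg$region_id, crop = cr,
                 start_doy = tw$start_doy, end_doy = tw$end_doy)
    }))
  }))
  bl <- data.frame(region_id = vapply(config$regions, `[[`, "", "region_id"),
                   baseline_year = vapply(config$regions, `[[`, 1L,
                                          "baseline_year"))
  truth <- structure(list(thresholds = thr, windows = win, baseline = bl,
                          areas = NULL, step_days = config$composite_step_days),
                     class = "synthetic_truth")
  truth$areas <- true_area_table(
    if (config$fill_fraction > 0) mask_invalid(cube, config$fill_value) else cube,
    mask, truth)
  list(cube = cube, mask = mask, truth = truth)
}

crop_region_mask <- function(mask, crop, region_id) {
  mask$masks[[crop]] & !is.na(mask$region) & mask$region == region_id
}

# Noise-free impacted-area table implied by the truth thresholds/windows,
# using the same indicator rule as extracted_area().
true_area_table <- function(cube, mask, truth) {
  out <- list()
  for (rid in unique(truth$thresholds$region_id)) {
    bl_year <- truth$baseline$baseline_year[truth$baseline$region_id == rid]
    crops <- unique(truth$windows$crop[truth$windows$region_id == rid])
    per_crop <- lapply(crops, function(cr) {
      w <- truth$windows[truth$windows$region_id == rid &
                           truth$windows$crop == cr, ]
      tw <- time_window(w$start_doy, w$end_doy, truth$step_days)
      cm <- crop_region_mask(mask, cr, rid)
      base_wm <- window_mean(cube, tw, bl_year, cm)
      list(crop = cr, tw = tw, cm = cm, base_wm = base_wm)
    })
    for (deg in DEGREES) {
      for (yr in cube$years) {
        area <- 0
        for (pc in per_crop) {
          Tst <- truth$thresholds$T_percent[
            truth$thresholds$region_id == rid &
              truth$thresholds$crop == pc$crop &
              truth$thresholds$degree == deg]
          wm <- window_mean(cube, pc$tw, yr, pc$cm)
          area <- area + extracted_area(wm, pc$base_wm, Tst, cube$grid)
        }
        out[[length(out) + 1L]] <- data.frame(
          region_id = rid, year = yr, degree = deg, area_thousand_ha = area)
      }
    }
  }
  do.call(rbind, out)
}

#' Derive historical drought-area statistics from a synthetic scene
#'
#' Emulates annual published drought-statistics tables: for each (region,
#' year, severity degree) the statistic is the area extracted from the cube
#' under the region's truth thresholds and windows — the same indicator rule
#' as [extracted_area()] — in thousand hectares, multiplied by a mean-one
#' lognormal noise factor with coefficient of variation `stats_noise_cv`
#' (factor identically 1 when the CV is 0). The baseline year is then clamped
#' to the per-(region, degree) series minimum so it stays the weakest-impact
#' year of the series.
#'
#' @param cube The `lai_cube` the pipeline will calibrate on (pass the same
#'   smoothed cube to both this function and the calibration for exact
#'   noise-free consistency).
#' @param mask The `crop_mask`.
#' @param truth The `synthetic_truth`.
#' @param stats_noise_cv Unitless CV `>= 0`.
#' @param seed Optional integer seed for the noise draw.
#' @return Data frame (class `historical_stats`) with columns `region_id`,
#'   `year`, `degree`, `area_thousand_ha`.
#' @export
derive_historical_stats <- function(cube, mask, truth, stats_noise_cv = 0,
                                    seed = NULL) {
  if (stats_noise_cv < 0) stop("stats_noise_cv must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  stats <- true_area_table(cube, mask, truth)
  if (stats_noise_cv > 0) {
    sdlog <- sqrt(log(1 + stats_noise_cv^2))
    fac <- stats::rlnorm(nrow(stats), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    stats$area_thousand_ha <- stats$area_thousand_ha * fac
  }
  for (rid in unique(stats$region_id)) {
    bl <- truth$baseline$baseline_year[truth$baseline$region_id == rid]
    for (deg in DEGREES) {
      sel <- stats$region_id == rid & stats$degree == deg
      stats$area_thousand_ha[sel & stats$year == bl] <-
        min(stats$area_thousand_ha[sel])
    }
  }
  class(stats) <- c("historical_stats", "data.frame")
  stats
}

#' Crop mask for a given year
#'
#' Crop masks are usually static matrices, but a crop may carry one mask per
#' year (a list keyed by year, as with annually mapped early-rice area). A
#' missing year falls back to the latest earlier year — the extrapolation rule
#' used when a final year's coverage map is carried forward from the previous
#' year.
#'
#' @param mask A `crop_mask`.
#' @param crop Crop label.
#' @param year Calendar year.
#' @return Logical matrix.
#' @export
mask_for_year <- function(mask, crop, year) {
  m <- mask$masks[[crop]]
  if (is.null(m)) stop("no mask for crop ", crop)
  if (is.matrix(m)) return(m)
  yrs <- as.integer(names(m))
  if (year %in% yrs) return(m[[as.character(year)]])
  prev <- yrs[yrs < year]
  if (!length(prev)) stop("no mask available for crop ", crop, " at or before ",
                          year)
  m[[as.character(max(prev))]]
}
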