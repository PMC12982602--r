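# End-to-end pipeline orchestration: a validated configuration drives the
# simulate -> preprocess -> calibrate -> extract -> validate stages, every
# output directory carries a provenance sidecar (config hash, seed, package
# version), and deterministic stages are bit-identical across reruns with the
# same configuration.

# 32-bit FNV-1a over the UTF-8 bytes of a string, as 8 hex digits. Exact in
# double arithmetic: the XOR runs on the low 31 bits (the folded byte only
# touches the low 8), and the 32-bit modular product is split into 16-bit
# halves to stay below 2^53.
fnv1a_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 0x811c9dc5
  for (b in bytes) {
    top <- h - (h %% 2147483648)
    h <- top + bitwXor(as.integer(h %% 2147483648), b)
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (((hi * 16777619) %% 65536) * 65536 + lo * 16777619) %% 4294967296
  }
  lo <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo) / 65536), as.integer(lo))
}

config_hash <- function(config) {
  fnv1a_hash(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              force = TRUE))
}

#' Build and validate a pipeline configuration
#'
#' Accepts a YAML file path or a list. Recognised fields: `scenario`
#' (`"default"` or `"reduced"`), `seed`, `noise_sd`, `stats_noise_cv`,
#' `smoothing` (`window_length`, `polyorder`), `thresholds` (`min`, `max`,
#' `step`), `window_scope`, `selection`, `enforce_nesting`, `baseline_years`
#' (named region -> year, optional; auto-selected otherwise), `map_years`
#' (optional subset of years to map).
#'
#' @param config Path to a YAML file or a list.
#' @return Validated config list of class `pipeline_config` (threshold grid
#'   expanded, scenario simulation config attached).
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defaults <- list(scenario = "default", seed = 1L, noise_sd = NULL,
                   stats_noise_cv = NULL,
                   smoothing = list(window_length = 3L, polyorder = 3L),
                   thresholds = list(min = 0, max = 100, step = 1),
                   window_scope = "per_crop", selection = "rmse_r",
                   enforce_nesting = FALSE, baseline_years = NULL,
                   map_years = NULL)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  th <- config$thresholds
  stopifnot(th$min >= 0, th$max <= 100, th$min < th$max, th$step > 0)
  if (abs((th$max - th$min) / th$step - round((th$max - th$min) / th$step)) >
      1e-9)
    stop("threshold step must divide the grid range")
  config$threshold_grid <- seq(th$min, th$max, by = th$step)
  config$window_scope <- match.arg(config$window_scope,
                                   c("per_crop", "per_degree"))
  config$selection <- match.arg(config$selection, c("rmse_r", "r_rmse"))
  sim_args <- list(seed = config$seed)
  if (!is.null(config$noise_sd)) sim_args$noise_sd <- config$noise_sd
  if (!is.null(config$stats_noise_cv))
    sim_args$stats_noise_cv <- config$stats_noise_cv
  config$sim <- switch(config$scenario,
                       default = do.call(scenario_default, sim_args),
                       reduced = do.call(scenario_reduced, sim_args),
                       stop("unknown scenario '", config$scenario,
                            "' (use \"default\" or \"reduced\")"))
  class(config) <- c("pipeline_config", "list")
  config
}

write_stats_csv <- function(stats, path) {
  utils::write.csv(as.data.frame(stats)[c("region_id", "year", "degree",
                                          "area_thousand_ha")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a historical-statistics CSV
#'
#' Columns `region_id`, `year`, `degree`, `area_thousand_ha`.
#'
#' @param path CSV path.
#' @return A `historical_stats` data frame.
#' @export
read_stats_csv <- function(path) {
  s <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("region_id", "year", "degree", "area_thousand_ha")
  if (!all(need %in% names(s)))
    stop("statistics CSV must have columns ", paste(need, collapse = ", "))
  class(s) <- c("historical_stats", "data.frame")
  s
}

#' Write an LAI cube as a directory of GeoTIFFs
#'
#' One float32 GeoTIFF per (year, composite) named `lai_{year}_{doy}.tif`
#' (invalid entries stored as NaN) plus a JSON manifest with the calendar,
#' years and grid.
#'
#' @param cube A `lai_cube`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_lai_cube <- function(cube, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  g <- cube$grid
  jsonlite::write_json(
    list(years = cube$years, composite_doys = cube$composite_doys,
         smoothed = isTRUE(cube$smoothed),
         grid = unclass(g)),
    file.path(dir, "cube.json"), auto_unbox = TRUE, digits = NA)
  for (yi in seq_along(cube$years)) {
    for (ci in seq_along(cube$composite_doys)) {
      m <- cube$values[, , ci, yi]
      m[!cube$valid[, , ci, yi]] <- NA_real_
      write_geotiff(m, file.path(dir, sprintf("lai_%d_%03d.tif",
                                              cube$years[yi],
                                              cube$composite_doys[ci])),
                    g, type = "float32")
    }
  }
  invisible(dir)
}

#' Read an LAI cube written by [write_lai_cube()]
#'
#' @param dir Directory with `cube.json` and the per-composite GeoTIFFs.
#' @return A `lai_cube` (float32 precision).
#' @export
read_lai_cube <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "cube.json"), simplifyVector = TRUE)
  g <- do.call(lai_grid, as.list(mf$grid))
  ny <- length(mf$years); ncomp <- length(mf$composite_doys)
  values <- array(0, c(g$nrow, g$ncol, ncomp, ny))
  valid <- array(TRUE, c(g$nrow, g$ncol, ncomp, ny))
  for (yi in seq_len(ny)) {
    for (ci in seq_len(ncomp)) {
      r <- read_geotiff(file.path(dir, sprintf("lai_%d_%03d.tif",
                                               mf$years[yi],
                                               mf$composite_doys[ci])))
      bad <- is.na(r$values)
      v <- r$values; v[bad] <- 0
      values[, , ci, yi] <- v
      valid[, , ci, yi] <- !bad
    }
  }
  structure(list(values = values, valid = valid,
                 composite_doys = as.integer(mf$composite_doys),
                 years = as.integer(mf$years), grid = g,
                 smoothed = isTRUE(mf$smoothed)),
            class = "lai_cube")
}

write_masks <- function(mask, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (cr in names(mask$masks)) {
    m <- mask$masks[[cr]]
    if (is.matrix(m) && any(m))
      write_geotiff(matrix(as.integer(m), nrow(m)),
                    file.path(dir, paste0("crop_", cr, ".tif")),
                    mask$grid, type = "uint8")
  }
  reg <- match(mask$region, mask$region_ids)
  reg[is.na(reg)] <- 0L
  write_geotiff(matrix(reg, nrow(mask$region)),
                file.path(dir, "regions.tif"), mask$grid, type = "uint8",
                nodata = 0)
  jsonlite::write_json(list(region_ids = mask$region_ids),
                       file.path(dir, "masks.json"), auto_unbox = FALSE)
  invisible(dir)
}

read_masks <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "masks.json"),
                            simplifyVector = TRUE)
  rg <- read_geotiff(file.path(dir, "regions.tif"))
  region <- matrix(mf$region_ids[ifelse(rg$values == 0L, NA, rg$values)],
                   nrow(rg$values))
  masks <- stats::setNames(lapply(CROPS, function(cr) {
    p <- file.path(dir, paste0("crop_", cr, ".tif"))
    if (file.exists(p)) read_geotiff(p)$values == 1L
    else matrix(FALSE, rg$grid$nrow, rg$grid$ncol)
  }), CROPS)
  structure(list(masks = masks, region = region,
                 region_ids = mf$region_ids, grid = rg$grid),
            class = "crop_mask")
}

write_truth <- function(truth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(truth$thresholds, file.path(dir, "truth_thresholds.csv"),
                   row.names = FALSE)
  utils::write.csv(truth$windows, file.path(dir, "truth_windows.csv"),
                   row.names = FALSE)
  utils::write.csv(truth$baseline, file.path(dir, "truth_baseline.csv"),
                   row.names = FALSE)
  utils::write.csv(truth$areas, file.path(dir, "truth_areas.csv"),
                   row.names = FALSE)
  invisible(dir)
}

read_truth <- function(dir, step_days = 8L) {
  structure(list(
    thresholds = utils::read.csv(file.path(dir, "truth_thresholds.csv")),
    windows = utils::read.csv(file.path(dir, "truth_windows.csv")),
    baseline = utils::read.csv(file.path(dir, "truth_baseline.csv")),
    areas = utils::read.csv(file.path(dir, "truth_areas.csv")),
    step_days = step_days), class = "synthetic_truth")
}

need_artifact <- function(path, producer) {
  if (!file.exists(path))
    stop("missing artifact '", basename(path), "'; run stage '", producer,
         "' first", call. = FALSE)
  path
}

#' Run the drought-impact pipeline
#'
#' Executes the requested stages in canonical order (simulate, preprocess,
#' calibrate, extract, validate), passing artifacts in memory within one call
#' and reading them from `out_dir` when a stage is run on its own. Every run
#' writes a provenance sidecar (`provenance.json` with the config hash, seed
#' and package version); a run into a directory holding a different
#' configuration's outputs stops unless `overwrite = TRUE`. Deterministic
#' stages are bit-identical across reruns of the same configuration.
#'
#' @param config A [pipeline_config()], a list, or a YAML path.
#' @param stages Subset of `c("simulate", "preprocess", "calibrate",
#'   "extract", "validate")`.
#' @param out_dir Output directory.
#' @param overwrite Allow writing over outputs of a different configuration.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the artifacts produced (`stats`, `calib`,
#'   `validation`, `recovery`, `map_files`, ...).
#' @export
run_pipeline <- function(config, stages = c("simulate", "preprocess",
                                            "calibrate", "extract",
                                            "validate"),
                         out_dir, overwrite = FALSE, quiet = FALSE) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  order_all <- c("simulate", "preprocess", "calibrate", "extract", "validate")
  stages <- order_all[order_all %in% match.arg(stages, order_all,
                                               several.ok = TRUE)]
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)

  hash <- config_hash(unclass(config)[setdiff(names(config), "sim")])
  prov_path <- file.path(out_dir, "provenance.json")
  if (file.exists(prov_path)) {
    prev <- jsonlite::read_json(prov_path)
    if (!identical(prev$config_hash, hash) && !overwrite)
      stop("out_dir holds outputs of a different configuration (hash ",
           prev$config_hash, " != ", hash,
           "); use overwrite = TRUE to replace them")
  }
  jsonlite::write_json(
    list(config_hash = hash, seed = config$seed,
         package_version = as.character(utils::packageVersion("droughtlai"))),
    prov_path, auto_unbox = TRUE)

  sim <- config$sim
  st <- new.env(parent = emptyenv())
  out <- list()

  if ("simulate" %in% stages) {
    say("simulate: generating scene (seed ", sim$seed, ")")
    scene <- generate_lai_cube(sim)
    stats <- derive_historical_stats(scene$cube, scene$mask, scene$truth,
                                     sim$stats_noise_cv,
                                     seed = sim$seed + 1L)
    write_lai_cube(scene$cube, file.path(out_dir, "cube"))
    write_masks(scene$mask, file.path(out_dir, "masks"))
    write_truth(scene$truth, file.path(out_dir, "truth"))
    write_stats_csv(stats, file.path(out_dir, "stats.csv"))
    st$cube_raw <- scene$cube; st$mask <- scene$mask
    st$truth <- scene$truth; st$stats <- stats
    out$stats <- stats
  }

  get_mask <- function() {
    if (is.null(st$mask))
      st$mask <- read_masks(dirname(need_artifact(
        file.path(out_dir, "masks", "masks.json"), "simulate")))
    st$mask
  }
  get_stats <- function() {
    if (is.null(st$stats))
      st$stats <- read_stats_csv(need_artifact(file.path(out_dir,
                                                         "stats.csv"),
                                               "simulate"))
    st$stats
  }

  if ("preprocess" %in% stages) {
    if (is.null(st$cube_raw))
      st$cube_raw <- read_lai_cube(dirname(need_artifact(
        file.path(out_dir, "cube", "cube.json"), "simulate")))
    say("preprocess: fill masking + Savitzky-Golay smoothing")
    cube <- mask_invalid(st$cube_raw, sim$fill_value)
    cube <- smooth_cube(cube, config$smoothing$window_length,
                        config$smoothing$polyorder)
    write_lai_cube(cube, file.path(out_dir, "cube_smoothed"))
    st$cube <- cube
  }
  get_cube <- function() {
    if (is.null(st$cube))
      st$cube <- read_lai_cube(dirname(need_artifact(
        file.path(out_dir, "cube_smoothed", "cube.json"), "preprocess")))
    st$cube
  }

  if ("calibrate" %in% stages) {
    say("calibrate: grid search over windows x thresholds")
    bl <- if (!is.null(config$baseline_years))
      unlist(config$baseline_years) else NULL
    calib <- calibrate_all(get_cube(), get_mask(), get_stats(),
                           scenario_growing_seasons(sim),
                           baseline_years = bl,
                           thresholds = config$threshold_grid,
                           window_scope = config$window_scope,
                           selection = config$selection)
    utils::write.csv(as.data.frame(calib),
                     file.path(out_dir, "calibration.csv"), row.names = FALSE)
    utils::write.csv(attr(calib, "ea_series"),
                     file.path(out_dir, "ea_series.csv"), row.names = FALSE)
    st$calib <- calib
    out$calib <- calib
  }
  get_calib <- function() {
    if (is.null(st$calib)) {
      p <- need_artifact(file.path(out_dir, "calibration.csv"), "calibrate")
      calib <- utils::read.csv(p, stringsAsFactors = FALSE)
      attr(calib, "ea_series") <- utils::read.csv(
        file.path(out_dir, "ea_series.csv"))
      class(calib) <- c("calibration_result", "data.frame")
      st$calib <- calib
    }
    st$calib
  }

  if ("extract" %in% stages) {
    calib <- get_calib(); cube <- get_cube(); mask <- get_mask()
    years <- if (!is.null(config$map_years)) config$map_years else cube$years
    crops <- unique(calib$crop)
    map_dir <- file.path(out_dir, "maps")
    say("extract: writing ", length(crops) * 3 * length(years),
        " impact rasters")
    files <- character(0); summaries <- list()
    for (yr in years) {
      rasters <- list()
      for (cr in crops) {
        for (deg in DEGREES)
          rasters[[paste(cr, deg)]] <- classify(cube, mask, calib, cr, deg, yr)
        if (config$enforce_nesting) {
          nst <- check_nesting(rasters[[paste(cr, "DC")]],
                               rasters[[paste(cr, "DD")]],
                               rasters[[paste(cr, "CF")]], enforce = TRUE)
          rasters[[paste(cr, "DC")]] <- nst$dc
          rasters[[paste(cr, "DD")]] <- nst$dd
          rasters[[paste(cr, "CF")]] <- nst$cf
        }
      }
      for (r in rasters) {
        files <- c(files, write_impact_tiff(r, map_dir))
        summaries[[length(summaries) + 1L]] <- impact_area_summary(r, mask)
      }
    }
    area_summary <- do.call(rbind, summaries)
    utils::write.csv(area_summary, file.path(out_dir, "area_summary.csv"),
                     row.names = FALSE)
    out$map_files <- files
    out$area_summary <- area_summary
  }

  if ("validate" %in% stages) {
    say("validate: EA-vs-HA consistency and recovery tables")
    calib <- get_calib()
    vt <- validate_series(calib, get_stats())
    utils::write.csv(vt, file.path(out_dir, "validation.csv"),
                     row.names = FALSE)
    out$validation <- vt
    truth_path <- file.path(out_dir, "truth", "truth_thresholds.csv")
    if (file.exists(truth_path)) {
      if (is.null(st$truth))
        st$truth <- read_truth(file.path(out_dir, "truth"),
                               sim$composite_step_days)
      rec <- recovery_summary(st$truth, calib)
      utils::write.csv(rec, file.path(out_dir, "recovery.csv"),
                       row.names = FALSE)
      out$recovery <- rec
    }
  }

  invisible(out)
}
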