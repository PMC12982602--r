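# Bundled study scenarios.
#
# These fix the synthetic study conditions used throughout the package's
# experiments: a two-region, two-crop scene spanning 2006-2020 for the main
# recovery experiment, and a one-region scene for Monte-Carlo replication.
# Event calendars, fractions and depressions are part of the scenario
# definition, not tuning knobs: each crop sees several distinct drought years
# of varied extent and intensity, the per-pixel depression spread (0.8) gives
# a continuum of LAI ratios so the truth threshold is identifiable on the 1%
# grid, and 2013 is kept event-free as the designed baseline year.

#' Default two-region study scenario
#'
#' A 24 x 40 pixel 500 m scene over 2006-2020. Region R1 grows autumn-harvest
#' crops only (growing season DOY 145-273, the span that yields 153 candidate
#' windows); region R2 grows summer- and autumn-harvest crops with partial
#' double cropping (every pixel carries the autumn crop, 60% also the summer
#' crop). Each crop has 4-5 drought years of varied extent (25-60% of pixels)
#' and mean depression 0.4-0.55.
#'
#' @param seed Integer RNG seed.
#' @param noise_sd Per-composite Gaussian LAI noise (default 0: exact scene).
#' @param stats_noise_cv CV of the lognormal noise on derived statistics
#'   (default 0).
#' @return A [simulation_config()].
#' @export
scenario_default <- function(seed = 1L, noise_sd = 0, stats_noise_cv = 0) {
  r1 <- region_spec(
    region_id = "R1", row_range = c(1, 24), col_range = c(1, 20),
    crops = "autumn",
    growing_season = list(autumn = c(145, 273)),
    truth_thresholds = list(autumn = c(DC = 80, DD = 60, CF = 40)),
    truth_windows = list(autumn = time_window(201, 233)),
    baseline_year = 2013,
    drought_events = data.frame(
      year = c(2007, 2009, 2011, 2016, 2018),
      crop = "autumn",
      fraction = c(0.50, 0.30, 0.25, 0.60, 0.35),
      depression = c(0.50, 0.45, 0.55, 0.50, 0.40)))
  r2 <- region_spec(
    region_id = "R2", row_range = c(1, 24), col_range = c(21, 40),
    crops = c("summer", "autumn"),
    growing_season = list(summer = c(65, 177), autumn = c(145, 273)),
    truth_thresholds = list(summer = c(DC = 85, DD = 65, CF = 45),
                            autumn = c(DC = 78, DD = 58, CF = 38)),
    truth_windows = list(summer = time_window(105, 137),
                         autumn = time_window(209, 241)),
    baseline_year = 2013,
    drought_events = data.frame(
      year = c(2006, 2010, 2014, 2019, 2008, 2012, 2016, 2019),
      crop = rep(c("summer", "autumn"), each = 4),
      fraction = c(0.40, 0.50, 0.30, 0.45, 0.50, 0.35, 0.55, 0.30),
      depression = c(0.50, 0.45, 0.55, 0.50, 0.50, 0.45, 0.50, 0.50)),
    crop_fraction = c(summer = 0.6, autumn = 1))
  simulation_config(
    seed = seed, grid = lai_grid(24, 40), years = 2006:2020,
    regions = list(r1, r2), noise_sd = noise_sd,
    stats_noise_cv = stats_noise_cv, depression_spread = 0.8,
    event_profile_sd = 0.6, phenology_shift_days = 10,
    annual_amplitude_cv = 0.1)
}

#' Reduced one-region scenario for Monte-Carlo replication
#'
#' A 16 x 16 pixel scene, one region growing the autumn crop (season DOY
#' 169-241, 55 candidate windows), four drought years, light LAI noise
#' (sd 0.02) and, by default, 5% lognormal noise on the statistics — the
#' configuration used for repeated noisy-recovery experiments.
#'
#' @param seed Integer RNG seed (vary per replicate).
#' @param stats_noise_cv CV of the statistics noise (default 0.05).
#' @param noise_sd Per-composite LAI noise (default 0.02).
#' @return A [simulation_config()].
#' @export
scenario_reduced <- function(seed = 1L, stats_noise_cv = 0.05,
                             noise_sd = 0.02) {
  r1 <- region_spec(
    region_id = "R1", row_range = c(1, 16), col_range = c(1, 16),
    crops = "autumn",
    growing_season = list(autumn = c(169, 241)),
    truth_thresholds = list(autumn = c(DC = 80, DD = 60, CF = 40)),
    truth_windows = list(autumn = time_window(193, 217)),
    baseline_year = 2013,
    drought_events = data.frame(
      year = c(2008, 2011, 2014, 2018),
      crop = "autumn",
      fraction = c(0.50, 0.30, 0.60, 0.40),
      depression = c(0.50, 0.55, 0.45, 0.50)))
  simulation_config(
    seed = seed, grid = lai_grid(16, 16), years = 2006:2020,
    regions = list(r1), noise_sd = noise_sd,
    stats_noise_cv = stats_noise_cv, depression_spread = 0.8,
    event_profile_sd = 0.6, phenology_shift_days = 10,
    annual_amplitude_cv = 0.1)
}

#' Growing seasons declared by a scenario
#'
#' @param config A [simulation_config()].
#' @return Named list region -> crop -> `c(doy_start, doy_end)`, the shape
#'   [calibrate_all()] expects.
#' @export
scenario_growing_seasons <- function(config) {
  out <- lapply(config$regions, function(rg) rg$growing_season[rg$crops])
  names(out) <- vapply(config$regions, `[[`, "", "region_id")
  out
}
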