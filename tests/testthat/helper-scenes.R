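# Small synthetic scenes shared across tests. Built in code at test time;
# kept deliberately tiny so the whole suite stays fast.

# One rectangular region, one crop, optional events; defaults give a clean
# deterministic scene (no noise, no spread) on a 6 x 10 grid.
tiny_config <- function(seed = 42, nrow = 6, ncol = 10,
                        years = 2010:2014, baseline_year = 2012,
                        events = data.frame(),
                        crops = "autumn",
                        season = c(145, 273),
                        truth_window = time_window(201, 233),
                        thresholds = c(DC = 80, DD = 60, CF = 40),
                        noise_sd = 0, stats_noise_cv = 0,
                        depression_spread = 0, event_profile_sd = 0,
                        phenology_shift_days = 0,
                        annual_amplitude_cv = 0, ...) {
  rg <- region_spec(
    region_id = "T1", row_range = c(1, nrow), col_range = c(1, ncol),
    crops = crops,
    growing_season = stats::setNames(rep(list(season), length(crops)), crops),
    truth_thresholds = stats::setNames(rep(list(thresholds), length(crops)),
                                       crops),
    truth_windows = stats::setNames(rep(list(truth_window), length(crops)),
                                    crops),
    baseline_year = baseline_year,
    drought_events = events)
  simulation_config(seed = seed, grid = lai_grid(nrow, ncol), years = years,
                    regions = list(rg), noise_sd = noise_sd,
                    stats_noise_cv = stats_noise_cv,
                    depression_spread = depression_spread,
                    event_profile_sd = event_profile_sd,
                    phenology_shift_days = phenology_shift_days,
                    annual_amplitude_cv = annual_amplitude_cv, ...)
}

tiny_scene <- function(...) generate_lai_cube(tiny_config(...))

# brute-force oracle for extracted_area: explicit per-pixel loop
brute_area <- function(actual, baseline, T, grid) {
  n <- 0L
  for (i in seq_along(actual)) {
    a <- actual[i]; b <- baseline[i]
    if (is.na(a) || is.na(b) || b <= 0) next
    if (a <= (T / 100) * b) n <- n + 1L
  }
  n * pixel_area_kha(grid)
}

# brute-force Savitzky-Golay oracle: per-position least-squares polynomial
# fit over the window (edge positions use the first/last full window and
# evaluate the fitted polynomial off-centre)
brute_sg <- function(x, window, order) {
  n <- length(x)
  h <- (window - 1) / 2
  out <- numeric(n)
  for (t in seq_len(n)) {
    lo <- min(max(t - h, 1), n - window + 1)
    idx <- lo:(lo + window - 1)
    fit <- stats::lm(y ~ stats::poly(i, order, raw = TRUE),
                     data.frame(i = idx, y = x[idx]))
    out[t] <- stats::predict(fit, data.frame(i = t))
  }
  out
}
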