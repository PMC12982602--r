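test_that("baseline-year selection minimises the summed degree areas with an
           earlier-year tie-break", {
  mk <- function(years, dc, dd, cf)
    structure(data.frame(region_id = "A", year = rep(years, 3),
                         degree = rep(c("DC", "DD", "CF"), each = length(years)),
                         area_thousand_ha = c(dc, dd, cf)),
              class = c("historical_stats", "data.frame"))
  s <- mk(2010:2012, c(100, 80, 90), c(50, 40, 60), c(10, 5, 20))
  expect_equal(select_baseline_year(s, "A"), 2011)  # minimal sum 125
  s0 <- mk(2010:2012, c(3, 0, 1), c(2, 0, 1), c(1, 0, 1))
  expect_equal(select_baseline_year(s0, "A"), 2011)
  tie <- mk(2010:2012, c(5, 5, 9), c(1, 1, 3), c(0, 0, 1))
  expect_equal(select_baseline_year(tie, "A"), 2010)
  incomplete <- mk(2010:2012, c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  incomplete <- incomplete[incomplete$degree != "CF", ]
  expect_error(select_baseline_year(incomplete, "A"), "incomplete")
})

test_that("extracted_area implements the indicator rule in thousand ha", {
  g <- lai_grid(2, 2)
  act <- matrix(c(1, 2, 3, 4), 2)
  base <- matrix(2, 2, 2)
  expect_equal(extracted_area(act, base, 50, g), 0.025)
  expect_equal(extracted_area(act, base, 0, g), 0)
  expect_equal(extracted_area(base, base, 100, g), 4 * 0.025)
  # 40 flagged pixels -> 1.0 thousand ha
  g8 <- lai_grid(8, 8)
  a8 <- matrix(1, 8, 8); b8 <- matrix(2, 8, 8)
  a8[1:40] <- 0.5; a8[41:64] <- 1.9
  expect_equal(extracted_area(a8, b8, 50, g8), 1.0)
  expect_error(extracted_area(matrix(1, 2, 2), matrix(1, 3, 3), 50, g),
               "different pixel sets")
})

test_that("extracted_area equals the brute-force per-pixel oracle on random
           grids", {
  set.seed(42)
  for (k in 1:100) {
    nr <- sample(2:10, 1); nc <- sample(2:10, 1)
    act <- matrix(runif(nr * nc, 0, 5), nr)
    base <- matrix(runif(nr * nc, 0, 5), nr)
    base[sample(length(base), nr %/% 2)] <- 0       # excluded pixels
    act[sample(length(act), nc %/% 2)] <- NA        # invalid pixels
    T <- sample(0:100, 1)
    g <- lai_grid(nr, nc)
    expect_equal(extracted_area(act, base, T, g),
                 brute_area(act, base, T, g))
  }
})

test_that("extracted_area is nondecreasing in the threshold", {
  set.seed(7)
  for (k in 1:5) {
    act <- matrix(runif(48, 0, 4), 6)
    base <- matrix(runif(48, 0.5, 4), 6)
    g <- lai_grid(6, 8)
    areas <- vapply(0:100, function(T) extracted_area(act, base, T, g), 0)
    expect_true(all(diff(areas) >= 0))
  }
})

test_that("estimated_series sums crops and anchors at the baseline area", {
  ea_s <- c(`2010` = 1, `2011` = 2)
  ea_a <- c(`2010` = 3, `2011` = 4)
  expect_equal(estimated_series(list(summer = ea_s, autumn = ea_a), 10),
               c(`2010` = 14, `2011` = 16))
  expect_equal(estimated_series(list(autumn = ea_s * 0), 0),
               c(`2010` = 0, `2011` = 0))
  expect_error(estimated_series(list(a = ea_s, b = c(`2012` = 1, `2011` = 1)),
                                0), "different year sets")
})

test_that("pearson_r and rmse match closed forms and the stats oracles", {
  expect_equal(pearson_r(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(pearson_r(c(1, 2, 3), c(3, 2, 1)), -1)
  ea <- c(1, 2, 4); ha <- c(2, 3, 9)
  expect_equal(pearson_r(ea, ha), stats::cor(ea, ha))
  expect_true(is.na(pearson_r(c(1, 1, 1), c(1, 2, 3))))
  expect_error(pearson_r(1:2, 1:2), "at least 3")

  expect_equal(rmse(c(1, 2), c(1, 2)), 0)
  expect_equal(rmse(c(1, 2), c(2, 4)), sqrt(2.5))
  set.seed(1)
  a <- rnorm(9); b <- rnorm(9)
  expect_equal(rmse(3 * a, 3 * b), 3 * rmse(a, b))
  expect_error(rmse(1:3, 1:4), "length mismatch")
})

test_that("constant historical series raise the zero-variance error", {
  ev <- data.frame(year = 2011, crop = "autumn", fraction = 0.4,
                   depression = 0.5)
  scene <- tiny_scene(events = ev)
  stats <- derive_historical_stats(scene$cube, scene$mask, scene$truth, 0)
  stats$area_thousand_ha <- 7
  wpc <- list(autumn = enumerate_windows(145, 273, 8))
  expect_error(calibrate_degree(scene$cube, scene$mask, stats, "T1", "DC",
                                wpc, 2012),
               "zero variance")
})

test_that("single-crop noise-free calibration recovers threshold, window and
           the exact truth series", {
  ev <- data.frame(year = c(2010, 2011, 2013), crop = "autumn",
                   fraction = c(0.5, 0.3, 0.6), depression = c(0.5, 0.55, 0.45))
  scene <- tiny_scene(nrow = 10, ncol = 14, events = ev,
                      depression_spread = 0.8, event_profile_sd = 0.6,
                      phenology_shift_days = 10, annual_amplitude_cv = 0.1)
  cube <- suppressWarnings(smooth_cube(scene$cube))
  stats <- derive_historical_stats(cube, scene$mask, scene$truth, 0)
  fits <- calibrate_region(cube, scene$mask, stats, "T1",
                           list(autumn = enumerate_windows(145, 273, 8)),
                           select_baseline_year(stats, "T1"))
  for (deg in c("DC", "DD", "CF")) {
    fit <- fits[[deg]]
    expect_equal(fit$R, 1, tolerance = 1e-9)
    expect_equal(fit$RMSE, 0, tolerance = 1e-9)
    expect_equal(unname(fit$EA), unname(fit$HA))
    expect_equal(fit$crops$autumn$T,
                 c(DC = 80, DD = 60, CF = 40)[[deg]])
    expect_equal(fit$crops$autumn$window$start_doy, 201)
    expect_equal(fit$crops$autumn$window$end_doy, 233)
  }
})

test_that("calibration is deterministic across repeated runs", {
  ev <- data.frame(year = c(2010, 2013), crop = "autumn",
                   fraction = c(0.5, 0.4), depression = c(0.5, 0.45))
  scene <- tiny_scene(nrow = 8, ncol = 8, events = ev,
                      depression_spread = 0.7, annual_amplitude_cv = 0.08,
                      noise_sd = 0.02)
  stats <- derive_historical_stats(scene$cube, scene$mask, scene$truth,
                                   0.05, seed = 77)
  gs <- list(T1 = list(autumn = c(145, 273)))
  a <- calibrate_all(scene$cube, scene$mask, stats, gs)
  b <- calibrate_all(scene$cube, scene$mask, stats, gs)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("per-degree and per-crop window scopes agree on noise-free data", {
  ev <- data.frame(year = c(2010, 2011, 2013), crop = "autumn",
                   fraction = c(0.5, 0.3, 0.6), depression = c(0.5, 0.55, 0.45))
  scene <- tiny_scene(nrow = 8, ncol = 10, events = ev,
                      depression_spread = 0.8, event_profile_sd = 0.6,
                      annual_amplitude_cv = 0.1)
  stats <- derive_historical_stats(scene$cube, scene$mask, scene$truth, 0)
  gs <- list(T1 = list(autumn = c(145, 273)))
  pc <- calibrate_all(scene$cube, scene$mask, stats, gs,
                      window_scope = "per_crop")
  pd <- calibrate_all(scene$cube, scene$mask, stats, gs,
                      window_scope = "per_degree")
  expect_equal(pc$T_percent, pd$T_percent)
  expect_equal(pc$R, rep(1, 3), tolerance = 1e-9)
  expect_equal(pd$RMSE, rep(0, 3), tolerance = 1e-9)
})

test_that("baseline identity: extraction in the baseline year is zero for any
           T < 100, so EA(baseline) = HA_base", {
  ev <- data.frame(year = 2011, crop = "autumn", fraction = 0.5,
                   depression = 0.5)
  scene <- tiny_scene(events = ev, depression_spread = 0.5)
  tw <- time_window(201, 233)
  base <- window_mean(scene$cube, tw, 2012, scene$mask$masks$autumn)
  for (T in c(0, 37, 64, 99))
    expect_equal(extracted_area(base, base, T, scene$cube$grid), 0)
  stats <- derive_historical_stats(scene$cube, scene$mask, scene$truth, 0)
  fit <- calibrate_degree(scene$cube, scene$mask, stats, "T1", "DC",
                          list(autumn = enumerate_windows(145, 273, 8)), 2012)
  ha_base <- stats$area_thousand_ha[stats$year == 2012 &
                                      stats$degree == "DC"]
  expect_equal(unname(fit$EA["2012"]), ha_base)
})
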