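test_that("perfect agreement gives R = 1 and RMSE = 0 everywhere", {
  ea <- data.frame(region_id = rep(c("A", "B"), each = 9),
                   degree = rep(rep(c("DC", "DD", "CF"), each = 3), 2),
                   year = rep(2010:2012, 6),
                   EA = rep(c(5, 2, 8), 6))
  stats <- ea; names(stats)[4] <- "area_thousand_ha"
  vt <- validate_series(ea, stats)
  expect_true(all(abs(vt$R - 1) < 1e-12))
  expect_true(all(vt$RMSE_thousand_ha == 0))
  expect_true(all(c("(pooled)", "A", "B") %in% vt$region_id))
})

test_that("validation metrics are exactly pearson_r/rmse on the joined
           series and row order does not matter", {
  set.seed(11)
  ea <- data.frame(region_id = "A", degree = "DC", year = 2010:2016,
                   EA = runif(7, 0, 10))
  stats <- data.frame(region_id = "A", degree = "DC", year = 2010:2016,
                      area_thousand_ha = runif(7, 0, 10))
  vt <- validate_series(ea, stats)
  direct_r <- pearson_r(ea$EA, stats$area_thousand_ha)
  direct_rmse <- rmse(ea$EA, stats$area_thousand_ha)
  expect_equal(vt$R[vt$region_id == "A"], direct_r)
  expect_equal(vt$RMSE_thousand_ha[vt$region_id == "A"], direct_rmse)
  shuffled <- validate_series(ea[sample(7), ], stats[sample(7), ])
  expect_equal(vt, shuffled)
  expect_error(validate_series(ea, transform(stats, year = year + 100)),
               "no overlapping")
})

test_that("pooled rows concatenate region-year pairs", {
  ea <- data.frame(region_id = rep(c("A", "B"), each = 3),
                   degree = "DC", year = rep(2010:2012, 2),
                   EA = c(1, 2, 3, 7, 9, 4))
  stats <- data.frame(region_id = rep(c("A", "B"), each = 3),
                      degree = "DC", year = rep(2010:2012, 2),
                      area_thousand_ha = c(2, 2, 4, 6, 10, 3))
  vt <- validate_series(ea, stats)
  pooled <- vt[vt$region_id == "(pooled)", ]
  expect_equal(pooled$n_years, 6)
  expect_equal(pooled$R, pearson_r(ea$EA, stats$area_thousand_ha))
  expect_equal(pooled$RMSE_thousand_ha,
               rmse(ea$EA, stats$area_thousand_ha))
})

test_that("recovery summary reports zero deltas when the truth is fed back
           and one row per (region, crop, degree)", {
  ev <- data.frame(year = c(2010, 2013), crop = "autumn",
                   fraction = c(0.5, 0.4), depression = c(0.5, 0.45))
  scene <- tiny_scene(nrow = 8, ncol = 8, events = ev,
                      depression_spread = 0.8, event_profile_sd = 0.5,
                      annual_amplitude_cv = 0.08)
  truth <- scene$truth
  fake_calib <- data.frame(
    region_id = truth$thresholds$region_id,
    crop = truth$thresholds$crop,
    degree = truth$thresholds$degree,
    T_percent = truth$thresholds$T_percent,
    window_start_doy = truth$windows$start_doy[
      match(truth$thresholds$crop, truth$windows$crop)],
    window_end_doy = truth$windows$end_doy[
      match(truth$thresholds$crop, truth$windows$crop)],
    R = 1, RMSE = 0, baseline_year = 2012)
  class(fake_calib) <- c("calibration_result", "data.frame")
  rec <- recovery_summary(truth, fake_calib)
  expect_equal(nrow(rec), 1 * 1 * 3)
  expect_true(all(rec$delta_T == 0))
  expect_true(all(rec$window_match))
})
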