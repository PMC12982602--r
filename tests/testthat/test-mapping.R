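# shared fixture: a calibrated two-event scene
mapping_fixture <- function() {
  ev <- data.frame(year = c(2010, 2013), crop = "autumn",
                   fraction = c(0.5, 0.35), depression = c(0.5, 0.45))
  scene <- tiny_scene(nrow = 8, ncol = 10, events = ev,
                      depression_spread = 0.8, event_profile_sd = 0.5,
                      annual_amplitude_cv = 0.08)
  stats <- derive_historical_stats(scene$cube, scene$mask, scene$truth, 0)
  calib <- calibrate_all(scene$cube, scene$mask, stats,
                         list(T1 = list(autumn = c(145, 273))))
  list(scene = scene, stats = stats, calib = calib)
}

test_that("classified areas equal extracted_area and codes are closed", {
  fx <- mapping_fixture()
  cube <- fx$scene$cube; mask <- fx$scene$mask
  for (deg in c("DC", "DD", "CF")) {
    r <- classify(cube, mask, fx$calib, "autumn", deg, 2010)
    expect_true(all(r$codes %in% c(0L, 1L, 2L, 3L, 99L)))
    expect_true(all(r$codes %in% c(0L, c(DC = 1L, DD = 2L, CF = 3L)[[deg]],
                                   99L)))
    row <- fx$calib[fx$calib$degree == deg, ]
    tw <- time_window(row$window_start_doy, row$window_end_doy)
    act <- window_mean(cube, tw, 2010, mask$masks$autumn)
    base <- window_mean(cube, tw, row$baseline_year, mask$masks$autumn)
    expect_equal(sum(r$codes %in% 1:3) * 0.025,
                 extracted_area(act, base, row$T_percent, cube$grid))
  }
})

test_that("baseline-year maps carry no impact flags and non-crop pixels are
           coded 99", {
  fx <- mapping_fixture()
  mask <- fx$scene$mask
  mask$masks$autumn[, 1] <- FALSE
  bl <- fx$calib$baseline_year[1]
  r <- classify(fx$scene$cube, mask, fx$calib, "autumn", "DC", bl)
  expect_true(all(r$codes[, 1] == 99L))
  expect_false(any(r$codes == 1L))
  dropped <- fx$calib[fx$calib$degree != "DC", ]
  class(dropped) <- class(fx$calib)
  expect_error(classify(fx$scene$cube, mask, dropped, "autumn", "DC", 2010),
               "no calibration")
})

test_that("ordered thresholds nest and swapped thresholds are counted as
           violations that enforcement repairs", {
  fx <- mapping_fixture()
  cube <- fx$scene$cube; mask <- fx$scene$mask
  maps <- lapply(c("DC", "DD", "CF"), function(d)
    classify(cube, mask, fx$calib, "autumn", d, 2010))
  chk <- check_nesting(maps[[1]], maps[[2]], maps[[3]])
  expect_equal(chk$violations, 0)

  # artificially swap: give CF the largest threshold
  swapped <- fx$calib
  swapped$T_percent[swapped$degree == "CF"] <-
    fx$calib$T_percent[fx$calib$degree == "DC"] + 10
  m2 <- lapply(c("DC", "DD", "CF"), function(d)
    classify(cube, mask, swapped, "autumn", d, 2010))
  chk2 <- check_nesting(m2[[1]], m2[[2]], m2[[3]])
  brute <- sum(m2[[3]]$codes == 3L & m2[[2]]$codes == 0L) +
    sum(m2[[3]]$codes == 3L & m2[[1]]$codes == 0L) +
    sum(m2[[2]]$codes == 2L & m2[[1]]$codes == 0L)
  expect_gt(chk2$violations, 0)
  expect_equal(chk2$violations, brute)
  fixed <- check_nesting(m2[[1]], m2[[2]], m2[[3]], enforce = TRUE)
  chk3 <- check_nesting(fixed$dc, fixed$dd, fixed$cf)
  expect_equal(chk3$violations, 0)
})

test_that("impact rasters follow the file naming convention and round trip
           losslessly", {
  fx <- mapping_fixture()
  r <- classify(fx$scene$cube, fx$scene$mask, fx$calib, "autumn", "DC", 2013)
  d <- file.path(tempdir(), "maps_test")
  p <- write_impact_tiff(r, d)
  expect_equal(basename(p), "Autumn_DC_2013.tif")
  back <- read_impact_tiff(p)
  expect_identical(back$codes, r$codes)
  expect_equal(unclass(back$grid), unclass(r$grid))
  expect_equal(back$crop, "autumn")
  expect_equal(back$degree, "DC")
  expect_equal(back$year, 2013L)
  g <- read_geotiff(p)
  expect_equal(g$nodata, 99)

  er <- r; er$crop <- "early_rice"
  expect_equal(basename(write_impact_tiff(er, d)), "ER_DC_2013.tif")
  sm <- r; sm$crop <- "summer"; sm$degree <- "CF"; sm$year <- 2006L
  expect_equal(basename(write_impact_tiff(sm, d)), "Summer_CF_2006.tif")
})

test_that("merging disjoint regions unions codes, keeps 99 elsewhere and
           preserves area totals", {
  fx <- mapping_fixture()
  r <- classify(fx$scene$cube, fx$scene$mask, fx$calib, "autumn", "DC", 2010)
  left <- r; left$codes[, 6:10] <- 99L
  right <- r; right$codes[, 1:5] <- 99L
  merged <- merge_regions(list(left, right))
  expect_identical(merged$codes, r$codes)
  blank <- r; blank$codes[] <- 99L
  expect_identical(merge_regions(list(r, blank))$codes, r$codes)
  expect_equal(sum(merged$codes == 1L),
               sum(left$codes == 1L) + sum(right$codes == 1L))
  clash <- right; clash$codes[, 1:5] <- 0L; clash$codes[1, 1] <- 1L
  left0 <- left; left0$codes[1, 1] <- 0L
  expect_error(merge_regions(list(left0, clash)), "non-identical")
})

test_that("the per-region area summary matches the flag counts", {
  fx <- mapping_fixture()
  r <- classify(fx$scene$cube, fx$scene$mask, fx$calib, "autumn", "DD", 2013)
  s <- impact_area_summary(r, fx$scene$mask)
  expect_equal(nrow(s), 1)
  expect_equal(s$area_thousand_ha, sum(r$codes == 2L) * 0.025)
})
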