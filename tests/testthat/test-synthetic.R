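test_that("generation is bit-identical for the same config and seed", {
  ev <- data.frame(year = 2011, crop = "autumn", fraction = 0.3,
                   depression = 0.4)
  a <- tiny_scene(seed = 9, events = ev, noise_sd = 0.05,
                  depression_spread = 0.5, event_profile_sd = 0.4,
                  phenology_shift_days = 6, annual_amplitude_cv = 0.05)
  b <- tiny_scene(seed = 9, events = ev, noise_sd = 0.05,
                  depression_spread = 0.5, event_profile_sd = 0.4,
                  phenology_shift_days = 6, annual_amplitude_cv = 0.05)
  expect_identical(a$cube$values, b$cube$values)
  expect_identical(a$mask$masks, b$mask$masks)
  expect_identical(a$truth$areas, b$truth$areas)
})

test_that("with no events and no noise every year equals the baseline", {
  scene <- tiny_scene()
  cube <- scene$cube
  for (yi in seq_along(cube$years))
    expect_identical(cube$values[, , , yi], cube$values[, , , 3])
  tw <- time_window(201, 233)
  base <- window_mean(cube, tw, 2012, scene$mask$masks$autumn)
  for (y in cube$years)
    expect_equal(window_mean(cube, tw, y, scene$mask$masks$autumn), base)
})

test_that("an event scales the affected pixels' window-mean LAI by exactly
           (1 - depression)", {
  ev <- data.frame(year = 2011, crop = "autumn", fraction = 0.25,
                   depression = 0.5)
  scene <- tiny_scene(nrow = 10, ncol = 10, events = ev)
  tw <- time_window(201, 233)
  act <- window_mean(scene$cube, tw, 2011, scene$mask$masks$autumn)
  base <- window_mean(scene$cube, tw, 2012, scene$mask$masks$autumn)
  ratio <- act / base
  n_half <- sum(abs(ratio - 0.5) < 1e-12)
  n_same <- sum(abs(ratio - 1) < 1e-12)
  expect_equal(n_half, 25L)
  expect_equal(n_same, 75L)
})

test_that("the per-pixel depression profile still scales the window mean
           exactly while varying composites", {
  ev <- data.frame(year = 2011, crop = "autumn", fraction = 0.4,
                   depression = 0.35)
  scene <- tiny_scene(nrow = 8, ncol = 8, events = ev, event_profile_sd = 0.7)
  tw <- time_window(201, 233)
  act <- window_mean(scene$cube, tw, 2011, scene$mask$masks$autumn)
  base <- window_mean(scene$cube, tw, 2012, scene$mask$masks$autumn)
  ratio <- act / base
  n_dep <- sum(abs(ratio - 0.65) < 1e-9)
  expect_equal(n_dep, round(0.4 * 64))
  # but individual composites are depressed unevenly
  ci <- match(tw$doys, scene$cube$composite_doys)
  aff <- which(abs(ratio - 0.65) < 1e-9)[1]
  per_comp <- scene$cube$values[, , ci, 2][rep(aff, length(ci)) +
                                             (seq_along(ci) - 1) * 64] /
    scene$cube$values[, , ci, 3][rep(aff, length(ci)) +
                                   (seq_along(ci) - 1) * 64]
  expect_gt(stats::sd(per_comp), 1e-3)
})

test_that("noise-free statistics equal an independent per-pixel brute-force
           count at 0.025 thousand ha per pixel", {
  ev <- data.frame(year = c(2011, 2013), crop = "autumn",
                   fraction = c(0.3, 0.5), depression = c(0.5, 0.3))
  scene <- tiny_scene(nrow = 8, ncol = 8, events = ev,
                      depression_spread = 0.6)
  stats <- derive_historical_stats(scene$cube, scene$mask, scene$truth, 0)
  cube <- scene$cube
  ci <- match(time_window(201, 233)$doys, cube$composite_doys)
  thr <- c(DC = 80, DD = 60, CF = 40)
  for (deg in names(thr)) {
    for (yr in cube$years) {
      n <- 0L
      for (px in which(scene$mask$masks$autumn)) {
        vals_y <- vals_b <- numeric(0)
        for (k in ci) {
          vals_y <- c(vals_y, cube$values[, , k, match(yr, cube$years)][px])
          vals_b <- c(vals_b, cube$values[, , k, match(2012,
                                                       cube$years)][px])
        }
        a <- mean(vals_y); b <- mean(vals_b)
        if (b > 0 && a <= (thr[[deg]] / 100) * b) n <- n + 1L
      }
      got <- stats$area_thousand_ha[stats$year == yr & stats$degree == deg]
      expect_equal(got, n * 0.025,
                   info = paste(deg, yr))
    }
  }
})

test_that("the baseline year holds the series minimum even under statistics
           noise", {
  ev <- data.frame(year = 2011, crop = "autumn", fraction = 0.5,
                   depression = 0.5)
  scene <- tiny_scene(events = ev, annual_amplitude_cv = 0.1)
  stats <- derive_historical_stats(scene$cube, scene$mask, scene$truth,
                                   stats_noise_cv = 0.2, seed = 5)
  for (deg in c("DC", "DD", "CF")) {
    s <- stats[stats$degree == deg, ]
    expect_equal(s$area_thousand_ha[s$year == 2012],
                 min(s$area_thousand_ha))
  }
})

test_that("truth statistics nest across severity degrees", {
  ev <- data.frame(year = c(2010, 2013), crop = "autumn",
                   fraction = c(0.6, 0.4), depression = c(0.5, 0.45))
  scene <- tiny_scene(nrow = 10, ncol = 12, events = ev,
                      depression_spread = 0.8, annual_amplitude_cv = 0.08)
  st <- scene$truth$areas
  for (yr in unique(st$year)) {
    a <- function(d) st$area_thousand_ha[st$year == yr & st$degree == d]
    expect_lte(a("CF"), a("DD"))
    expect_lte(a("DD"), a("DC"))
  }
})

test_that("deepening a drought event never shrinks any derived area", {
  mk <- function(d) {
    ev <- data.frame(year = 2011, crop = "autumn", fraction = 0.4,
                     depression = d)
    tiny_scene(seed = 3, nrow = 8, ncol = 8, events = ev)$truth$areas
  }
  lo <- mk(0.3); hi <- mk(0.55)
  expect_true(all(hi$area_thousand_ha >= lo$area_thousand_ha))
})

test_that("invalid configurations are rejected", {
  g <- lai_grid(6, 10)
  rg <- function(id, rows, cols)
    region_spec(id, rows, cols, "autumn",
                list(autumn = c(145, 273)),
                list(autumn = c(DC = 80, DD = 60, CF = 40)),
                list(autumn = time_window(201, 233)), 2012, data.frame())
  expect_error(simulation_config(1, g, 2010:2014,
                                 list(rg("A", c(1, 4), c(1, 10)),
                                      rg("B", c(3, 6), c(1, 10)))),
               "overlap")
  expect_error(region_spec("A", c(1, 4), c(1, 10), "autumn",
                           list(autumn = c(145, 273)),
                           list(autumn = c(DC = 80, DD = 60, CF = 40)),
                           list(autumn = time_window(201, 233)), 2012,
                           data.frame(year = 2011, crop = "summer",
                                      fraction = 0.5, depression = 0.5)),
               "does not grow")
  expect_error(region_spec("A", c(1, 4), c(1, 10), "autumn",
                           list(autumn = c(145, 273)),
                           list(autumn = c(DC = 80, DD = 60, CF = 40)),
                           list(autumn = time_window(201, 233)), 2012,
                           data.frame(year = 2012, crop = "autumn",
                                      fraction = 0.5, depression = 0.5)),
               "baseline year")
  expect_error(region_spec("A", c(1, 4), c(1, 10), "autumn",
                           list(autumn = c(145, 273)),
                           list(autumn = c(DC = 40, DD = 60, CF = 80)),
                           list(autumn = time_window(201, 233)), 2012,
                           data.frame()),
               "decrease")
  scene <- tiny_scene()
  expect_error(derive_historical_stats(scene$cube, scene$mask, scene$truth,
                                       -0.1), ">= 0")
})

test_that("annual per-year masks fall back to the latest earlier year", {
  scene <- tiny_scene()
  m2019 <- scene$mask$masks$autumn
  m2018 <- m2019; m2018[1, 1] <- FALSE
  scene$mask$masks$early_rice <- list(`2018` = m2018, `2019` = m2019)
  expect_identical(mask_for_year(scene$mask, "early_rice", 2019), m2019)
  expect_identical(mask_for_year(scene$mask, "early_rice", 2020), m2019)
  expect_identical(mask_for_year(scene$mask, "early_rice", 2018), m2018)
  expect_error(mask_for_year(scene$mask, "early_rice", 2017), "no mask")
  expect_identical(mask_for_year(scene$mask, "autumn", 2031),
                   scene$mask$masks$autumn)
})
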