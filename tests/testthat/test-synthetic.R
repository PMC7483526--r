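test_that("a flat configuration has constant intensity; bumps raise it at sunrise", {
  flat <- synthetic_config(lambda_day = 5, lambda_night = 5, bump_amp = 0,
                           season_amp = 0, lunar_effect = 1, water_effect = 1,
                           n_days = 3)
  tt <- parse_utc("2016-06-06") + seq(0, 3 * 86400 - 60, by = 600)
  lam <- intensity_at(tt, flat)
  expect_true(all(abs(lam - 5) < 1e-12))

  bumpy <- synthetic_config(lambda_day = 5, lambda_night = 5, bump_amp = 4,
                            season_amp = 0, n_days = 3)
  ev <- solar_events(as.Date("2016-06-07"), bumpy$site)
  sr_min <- dielPAM:::floor_minute(ev$sunrise)
  at_sunrise <- intensity_at(sr_min, bumpy)
  later <- intensity_at(sr_min + 6 * 3600, bumpy)
  expect_gte(at_sunrise, later)
  expect_gt(at_sunrise, 5 + 3)  # near the unit-peak kernel maximum
})

test_that("seasonal modulation has the configured summer/winter contrast", {
  cfg <- synthetic_config(lambda_day = 5, lambda_night = 5, bump_amp = 0,
                          season_amp = 0.4)
  s_jun <- intensity_at(parse_utc("2016-06-24 12:00:00"), cfg)
  s_dec <- intensity_at(parse_utc("2016-12-23 12:00:00"), cfg)
  expect_lt(abs(s_jun / s_dec - (1 + 0.4) / (1 - 0.4)), 0.02)
})

test_that("same seed and config reproduce the dataset bit for bit", {
  cfg <- preset_config("tiny")
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$clicks$records, d2$clicks$records)
  expect_identical(d1$water, d2$water)
  expect_identical(d1$deployments, d2$deployments)
  expect_identical(d1$truth$true_peak_angle, d2$truth$true_peak_angle)
  d3 <- simulate_dataset(preset_config("tiny", seed = 100))
  expect_false(identical(d1$clicks$records$clicks, d3$clicks$records$clicks))
})

test_that("simulated counts match the configured mean and are overdispersed", {
  cfg <- synthetic_config(lambda_day = 6, lambda_night = 6, bump_amp = 0,
                          season_amp = 0, period_sd = 0, bout_sd = 0,
                          dispersion = 0.8, n_days = 40, seed = 5)
  d <- simulate_dataset(cfg)
  x <- d$clicks$records$clicks
  expect_gt(length(x), 4.5e4)  # 40 days minus outages and retrieval gaps
  expect_lt(abs(mean(x) / 6 - 1), 0.02)
  expect_gt(var(x), mean(x) * 1.5)  # NB variance 6 + 36/0.8 >> mean
  # Poisson limit is recoverable
  cfgp <- synthetic_config(lambda_day = 6, lambda_night = 6, bump_amp = 0,
                           season_amp = 0, period_sd = 0, bout_sd = 0,
                           dispersion = Inf, n_days = 5, seed = 5)
  xp <- simulate_dataset(cfgp)$clicks$records$clicks
  expect_lt(var(xp) / mean(xp), 1.1)
})

test_that("the default year-long schedule injects retrieval gaps and outages", {
  cfg <- preset_config("strong_diel"); cfg$n_days <- 60L
  d <- simulate_dataset(cfg)
  expect_equal(sum(d$deployments$kind == "retrieval"), 8L)
  expect_gt(nrow(d$clicks$gaps), 8L)
  total_gap_min <- sum(as.numeric(d$clicks$gaps$end - d$clicks$gaps$start,
                                  units = "mins"))
  expect_gt(total_gap_min, 7 * 1440)  # two multi-day outages dominate
  # water level plausibility: bulk modest, quartile magnitudes ~10-20 cm
  q <- quantile(d$water$height_cm, c(.25, .75))
  expect_lt(q[1], 0); expect_gt(q[2], 0)
  expect_true(all(abs(q) < 30))
})

test_that("symmetric dawn/dusk bumps merge into an apparent midnight peak", {
  # the circular mean of two symmetric crepuscular bumps is their bisector
  # (solar midnight), even though the intensity there is at its base level:
  # the classic merging artifact of pooled dawn/dusk activity
  cfg <- preset_config("crepuscular_only"); cfg$n_days <- 90L
  d <- simulate_dataset(cfg)
  ang <- time_to_angle(d$clicks$records$timestamp)
  fit <- fit_vonmises(ang, d$clicks$records$clicks)
  ev <- solar_events(as.Date("2016-07-01"), cfg$site)
  solar_noon <- (as.numeric(ev$sunrise) + as.numeric(ev$sunset)) / 2
  midnight_angle <- (time_to_angle(as.POSIXct(solar_noon, origin = "1970-01-01",
                                              tz = "UTC")) + pi) %% (2 * pi)
  dist <- abs(((fit$mu - midnight_angle + pi) %% (2 * pi)) - pi)
  expect_lt(dist * 1440 / (2 * pi), 120)  # within 2 h of solar midnight
  # yet the intensity at the fitted peak is near the base rate, far below
  # the bump maxima at sunrise/sunset
  peak_t <- parse_utc("2016-07-01") + fit$mu / (2 * pi) * 86400
  sr_min <- dielPAM:::floor_minute(ev$sunrise)
  expect_lt(intensity_at(peak_t, cfg), 0.5 * intensity_at(sr_min, cfg))
})

test_that("fixtures round-trip through the readers and record their truth", {
  dir <- withr::local_tempdir()
  make_fixture("tiny", dir)
  cl <- read_click_minutes(file.path(dir, "clicks.csv"))
  wa <- read_water_level(file.path(dir, "waterlevel.csv"))
  dl <- read_deployment_log(file.path(dir, "deployments.csv"))
  tr <- jsonlite::read_json(file.path(dir, "truth.json"))
  d <- simulate_dataset(preset_config("tiny"))
  expect_equal(cl$records$clicks, d$clicks$records$clicks)
  expect_equal(wa$height_cm, d$water$height_cm)
  expect_equal(dl$kind, d$deployments$kind)
  expect_equal(tr$true_peak_angle, d$truth$true_peak_angle, tolerance = 1e-12)
  expect_equal(tr$config$seed, 99L)
  expect_error(make_fixture("nope", dir), "presets")
})
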