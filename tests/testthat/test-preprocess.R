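test_that("deployment edges are trimmed: 5 min after deployment, 2 min before retrieval", {
  t0 <- parse_utc("2016-06-06 12:00:00")
  s <- tiny_series(rep(1, 600))  # 12:00 .. 21:59
  log <- deployment_log(c(t0, t0 + 540 * 60), c("deployment", "retrieval"))
  tr <- trim_deployment_edges(s, log)
  gone <- setdiff(format_utc(s$records$timestamp),
                  format_utc(tr$records$timestamp))
  expect_equal(gone, format_utc(c(t0 + (0:4) * 60, t0 + (538:539) * 60)))
  # empty log is the identity; trimming is idempotent
  empty <- deployment_log(parse_utc(character(0)), character(0))
  expect_identical(trim_deployment_edges(s, empty), s)
  expect_identical(trim_deployment_edges(tr, log), tr)
})

test_that("light/dark segmentation tiles the span with alternating periods", {
  s <- ktd_site()
  span <- c(parse_utc("2016-06-06"), parse_utc("2016-06-07"))
  per <- segment_light_periods(span[1], span[2], s)
  expect_true(all(per$kind[-1] != per$kind[-nrow(per)]))
  expect_equal(as.numeric(per$start[1]), as.numeric(span[1]))
  expect_equal(as.numeric(per$end[nrow(per)]), as.numeric(span[2]))
  expect_true(all(as.numeric(per$end[-nrow(per)]) ==
                    as.numeric(per$start[-1])))
  # one full civil day: 1 full day period, parts of 2 nights
  expect_equal(sum(per$kind == "day" & !per$partial), 1L)
  expect_equal(sum(per$kind == "night"), 2L)
  # tiling: durations sum to span duration
  expect_equal(sum(as.numeric(per$end - per$start, units = "mins")),
               as.numeric(span[2] - span[1], units = "mins"))
})

test_that("a full year yields about 365 day and 365 night periods", {
  per <- segment_light_periods(parse_utc("2016-06-06"),
                               parse_utc("2017-06-06"), ktd_site())
  expect_true(abs(sum(per$kind == "day") - 365) <= 1)
  expect_true(abs(sum(per$kind == "night") - 365) <= 1)
  jun <- per[per$date_key == as.Date("2016-06-21") & per$kind == "day", ]
  dec <- per[per$date_key == as.Date("2016-12-21") & per$kind == "day", ]
  expect_gt(as.numeric(jun$end - jun$start, units = "hours") -
              as.numeric(dec$end - dec$start, units = "hours"), 9)
})

test_that("period summaries compute medians and flag incompleteness", {
  # synthetic periods over a plain minute grid (no ephemeris needed)
  t0 <- parse_utc("2016-06-06 00:00:00")
  s <- click_series(t0 + (0:9) * 60, c(0, 0, 4, 1, 2, 3, 9, 9, 9, 9))
  periods <- data.frame(kind = c("day", "night"),
                        start = c(t0, t0 + 3 * 60),
                        end = c(t0 + 3 * 60, t0 + 10 * 60),
                        date_key = as.Date("2016-06-06"),
                        partial = c(FALSE, FALSE))
  out <- summarise_periods(s, periods)
  expect_equal(out$median_cpm, c(0, 9))  # median(0,0,4); median(1,2,3,9,9,9,9)
  expect_true(all(out$complete))
  # knock one minute out of the second period -> incomplete
  s2 <- click_series(s$records$timestamp[-6], s$records$clicks[-6],
                     span_start = t0, span_end = t0 + 10 * 60)
  out2 <- summarise_periods(s2, periods)
  expect_false(out2$complete[2])
  expect_true(is.na(out2$median_cpm[2]))
  expect_true(out2$complete[1])
  # tolerance knob
  out3 <- summarise_periods(s2, periods, max_missing_minutes = 1)
  expect_true(out3$complete[2])
})

test_that("period medians agree with a sort-based oracle on random data", {
  set.seed(88)
  t0 <- parse_utc("2016-06-06 00:00:00")
  counts <- rnbinom(1000, size = 0.7, mu = 8)
  s <- click_series(t0 + (0:999) * 60, counts)
  periods <- data.frame(kind = "day", start = t0, end = t0 + 1000 * 60,
                        date_key = as.Date("2016-06-06"), partial = FALSE)
  got <- summarise_periods(s, periods)$median_cpm
  sorted <- sort(counts)
  oracle <- (sorted[500] + sorted[501]) / 2
  expect_equal(got, oracle)
})

test_that("crepuscular labelling covers 2 h before sunrise and after sunset, half-open", {
  s <- ktd_site()
  ev <- solar_events(as.Date("2016-06-21"), s)
  expect_true(label_crepuscular(ev$sunrise - 3600, s))
  expect_true(label_crepuscular(ev$sunset + 3599, s))
  expect_false(label_crepuscular(ev$sunrise + 60, s))
  expect_false(label_crepuscular(ev$sunset + 2 * 3600, s))
  expect_false(label_crepuscular(ev$sunrise - 2 * 3600 - 1, s))
  # window width knob
  expect_false(label_crepuscular(ev$sunrise - 3600, s, window_h = 0.5))
})

test_that("illumination bins are quarter-width, left-closed, last bin closed at 1", {
  expect_equal(discretise_illumination(c(0, 0.1, 0.25, 0.3, 0.5, 0.74, 0.75, 1)),
               c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L))
  expect_error(discretise_illumination(1.2), "\\[0, 1\\]")
})

test_that("water split puts 28 cm in the high group and -59 in low", {
  expect_equal(as.character(discretise_water(c(-59, 27.9, 28, 30, 115))),
               c("low", "low", "high", "high", "high"))
})

test_that("night covariates use the dark-period midpoint and the period median water level", {
  # a night whose midpoint is the catalogued 2016-06-20 full moon
  t0 <- parse_utc("2016-06-20 09:02:00")
  night <- data.frame(kind = "night", start = t0, end = t0 + 4 * 3600,
                      date_key = as.Date("2016-06-20"), partial = FALSE,
                      n_minutes = 240L, n_recorded = 240L, complete = TRUE,
                      median_cpm = 3)
  w <- water_level(t0 + (0:23) * 600, rep(50, 24))
  out <- attach_night_covariates(night, w)
  expect_equal(as.character(out$lunar_phase), "full")
  expect_equal(out$illum_bin, 4L)
  expect_equal(as.character(out$water_group), "high")
  # no water samples in the period -> NA water group, lunar intact
  w2 <- water_level(t0 + 10 * 3600, 50)
  out2 <- attach_night_covariates(night, w2)
  expect_true(is.na(out2$water_group))
  expect_equal(as.character(out2$lunar_phase), "full")
  # day rows never get covariates
  day <- night; day$kind <- "day"
  expect_true(is.na(attach_night_covariates(day, w)$lunar_phase))
})
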