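# Synthetic year generator. Emulates the structure the analysis assumes:
# overdispersed minute counts with elevated night rates, von Mises-shaped
# activity bumps locked to sunrise/sunset (so their clock time drifts with
# season), a multiplicative seasonal cycle peaking in late June, a
# tide-like water level with heavy-tailed surge, and logger gaps from a
# deployment/retrieval schedule. Ground truth derivable from the config is
# kept alongside the data for recovery tests.

#' Configuration for the synthetic generator
#'
#' @param lambda_day,lambda_night mean clicks/min in daylight and darkness.
#' @param bump_amp added mean clicks/min at the centre of the sunrise and
#'   sunset bumps.
#' @param bump_conc concentration of the bumps: a unit-peak von Mises-shaped
#'   kernel in minute-of-day distance from the event
#'   (`exp(conc * (cos(2*pi*d/1440) - 1))`).
#' @param season_amp multiplicative seasonal modulation amplitude;
#'   `s(date) = 1 + season_amp * cos(2*pi*(doy - doy_peak)/365.25)`.
#' @param doy_peak day-of-year of the seasonal maximum (default 175,
#'   late June).
#' @param dispersion negative-binomial size parameter (> 0, smaller is
#'   burstier); `Inf` gives Poisson counts.
#' @param lunar_effect,water_effect multiplicative covariate effects
#'   (default 1 = none): night rates scale by
#'   `1 + (lunar_effect - 1) * illumination` and by `water_effect` when the
#'   concurrent water level is in the high group.
#' @param period_sd per-period behavioural effect: each light/dark period
#'   gets an independent mean-one lognormal multiplier with standard
#'   deviation `period_sd` on the log scale (night-to-night and
#'   day-to-day variation in overall activity); 0 turns it off.
#' @param bout_sd,bout_tau_h behavioural "activity bout" modulation: a
#'   mean-one lognormal AR(1) process on a 30-min grid with stationary
#'   standard deviation `bout_sd` on the log scale and correlation time
#'   `bout_tau_h` hours multiplies the intensity. This is what makes
#'   per-period medians vary between periods the way real behavioural
#'   records do; `bout_sd = 0` turns it off.
#' @param start_date first simulated day (UTC midnight start).
#' @param n_days number of simulated days.
#' @param seed master seed; the same seed and config give bit-identical
#'   output. Independent sub-seeds feed the click, water and gap streams, so
#'   adding one stream never perturbs another.
#' @param site a [site()]; bumps and day/night follow its ephemeris.
#' @param gap_schedule `NULL` for the default schedule (single deployment
#'   for short runs; 8 mid-record retrievals with 20-60 min on land plus two
#'   multi-day technical outages totalling 7 days for runs of 30 days or
#'   more), or a list with elements `log` (a [deployment_log()]) and
#'   `outages` (data.frame `start`, `end`).
#' @return list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(lambda_day = 15, lambda_night = 45,
                             bump_amp = 45, bump_conc = 12,
                             season_amp = 0.4, doy_peak = 175,
                             dispersion = 0.6,
                             lunar_effect = 1, water_effect = 1,
                             period_sd = 0.6, bout_sd = 0.7, bout_tau_h = 3,
                             start_date = "2016-06-06", n_days = 365,
                             seed = 1, site = NULL, gap_schedule = NULL) {
  if (is.null(site)) site <- kerteminde()
  stopifnot(lambda_day >= 0, lambda_night >= 0, bump_amp >= 0,
            bump_conc > 0, season_amp >= 0, dispersion > 0, n_days >= 1,
            lunar_effect >= 0, water_effect >= 0, period_sd >= 0,
            bout_sd >= 0, bout_tau_h > 0, inherits(site, "pam_site"))
  structure(list(lambda_day = lambda_day, lambda_night = lambda_night,
                 bump_amp = bump_amp, bump_conc = bump_conc,
                 season_amp = season_amp, doy_peak = doy_peak,
                 dispersion = dispersion, lunar_effect = lunar_effect,
                 water_effect = water_effect, period_sd = period_sd,
                 bout_sd = bout_sd, bout_tau_h = bout_tau_h,
                 start_date = as.Date(start_date), n_days = as.integer(n_days),
                 seed = as.integer(seed), site = site,
                 gap_schedule = gap_schedule),
            class = "synthetic_config")
}

#' Preset synthetic configurations
#'
#' `strong_diel` is the reference year: night rate three times the day rate,
#' crepuscular bumps, summer seasonal maximum. `flat_null` is the
#' exchangeable null: constant expected rate (no diel, crepuscular,
#' seasonal, lunar or water structure) with overdispersion and bout
#' variability kept, so every randomisation statistic varies but its null
#' holds exactly. `crepuscular_only` has equal day/night base rates with
#' bumps only; `seasonal` exaggerates the seasonal cycle; `tiny` is a 3-day
#' strong-diel run for fast examples.
#'
#' @param name one of `"flat_null"`, `"strong_diel"`, `"crepuscular_only"`,
#'   `"seasonal"`, `"tiny"`.
#' @param seed optional master-seed override.
#' @return a [synthetic_config()].
#' @export
preset_config <- function(name, seed = NULL) {
  cfg <- switch(name,
    strong_diel = synthetic_config(seed = 42),
    flat_null = synthetic_config(lambda_day = 40, lambda_night = 40,
                                 bump_amp = 0, season_amp = 0, seed = 7),
    crepuscular_only = synthetic_config(lambda_day = 20, lambda_night = 20,
                                        bump_amp = 60, season_amp = 0.3,
                                        seed = 11),
    seasonal = synthetic_config(season_amp = 0.7, seed = 13),
    tiny = synthetic_config(n_days = 3, seed = 99),
    stop("unknown preset '", name, "'; presets: flat_null, strong_diel, ",
         "crepuscular_only, seasonal, tiny"))
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cfg
}

# seasonal modulation s(date)
season_factor <- function(dates, cfg) {
  doy <- as.integer(format(dates, "%j"))
  1 + cfg$season_amp * cos(2 * pi * (doy - cfg$doy_peak) / 365.25)
}

# core intensity: minute timestamps t (POSIXct UTC) with per-minute solar
# events already looked up; water height optional (for water_effect)
intensity_core <- function(t, cfg, sunrise, sunset, height_cm = NULL) {
  tn <- as.numeric(t)
  night <- !(tn >= as.numeric(sunrise) & tn < as.numeric(sunset))
  g <- function(event) {
    d <- (tn - as.numeric(event)) / MINUTE
    exp(cfg$bump_conc * (cos(2 * pi * d / 1440) - 1))
  }
  lam <- cfg$lambda_day + (cfg$lambda_night - cfg$lambda_day) * night +
    cfg$bump_amp * (g(sunrise) + g(sunset))
  lam <- lam * season_factor(local_date(t, cfg$site$utc_offset), cfg)
  if (cfg$lunar_effect != 1) {
    ill <- lunar_info(t)$illumination
    lam <- lam * ifelse(night, 1 + (cfg$lunar_effect - 1) * ill, 1)
  }
  if (cfg$water_effect != 1 && !is.null(height_cm)) {
    lam <- lam * ifelse(height_cm >= 28, cfg$water_effect, 1)
  }
  lam
}

#' Expected clicks per minute under a synthetic configuration
#'
#' @param t timestamp vector (`POSIXct` UTC or parseable).
#' @param cfg a [synthetic_config()].
#' @return numeric mean clicks/min at each timestamp (water effect, if any,
#'   is not applied here since it needs a realised water series).
#' @export
intensity_at <- function(t, cfg) {
  t <- parse_utc(t)
  dates <- local_date(t, cfg$site$utc_offset)
  ev <- solar_events(seq(min(dates), max(dates), by = "day"), cfg$site)
  i <- match(dates, ev$date)
  intensity_core(t, cfg, ev$sunrise[i], ev$sunset[i])
}

# default deployment schedule + technical outages
default_gap_schedule <- function(cfg, span_start, span_end, seed) {
  if (cfg$n_days < 30) {
    return(list(log = deployment_log(span_start, "deployment"),
                outages = data.frame(start = parse_utc(character(0)),
                                     end = parse_utc(character(0)))))
  }
  set.seed(seed)
  ret_days <- round(cfg$n_days * (1:8) / 9)
  ret <- span_start + ret_days * DAY + 10 * 3600       # 10:00 UTC
  downtime <- floor(stats::runif(8, 20, 61)) * MINUTE  # 20-60 min on land
  ev_t <- c(span_start, as.numeric(t(cbind(ret, ret + downtime))))
  ev_t <- as.POSIXct(as.numeric(ev_t), origin = "1970-01-01", tz = "UTC")
  kind <- c("deployment", rep(c("retrieval", "deployment"), 8))
  out_start <- span_start + round(cfg$n_days * c(0.40, 0.70)) * DAY
  outages <- data.frame(start = out_start, end = out_start + c(4, 3) * DAY)
  list(log = deployment_log(ev_t, kind), outages = outages)
}

#' Simulate a synthetic monitoring record
#'
#' Draws per-minute click counts as negative binomial with mean
#' `intensity_at()` and size `dispersion`, a 10-min water-level series
#' (semidiurnal harmonics with weak spring-neap lunar coupling plus a
#' heavy-tailed AR(1) surge, bulk within roughly +/-20 cm and occasional
#' ~1 m excursions), a deployment log, and the generating truth.
#'
#' @param cfg a [synthetic_config()].
#' @return list of class `"synthetic_dataset"`: `clicks` ([click_series()]),
#'   `water` ([water_level()]), `deployments` ([deployment_log()]), `truth`
#'   (list: the config, `true_peak_angle` — the circular mean direction of
#'   the noise-free intensity over the span, `true_peak_clock` in site local
#'   time, and `day_night_median_contrast` — median night minus median day
#'   intensity), `config`.
#' @examples
#' d <- simulate_dataset(preset_config("tiny"))
#' d$clicks
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  seeds <- sample.int(.Machine$integer.max, 4L)  # clicks, water, gaps, spare
  span_start <- parse_utc(cfg$start_date)
  span_end <- span_start + cfg$n_days * DAY
  t <- span_start + (seq_len(cfg$n_days * 1440L) - 1L) * MINUTE

  dates <- local_date(t, cfg$site$utc_offset)
  ev <- solar_events(seq(min(dates), max(dates), by = "day"), cfg$site)
  di <- match(dates, ev$date)
  sunrise <- ev$sunrise[di]; sunset <- ev$sunset[di]

  # water first (clicks may depend on it through water_effect)
  water <- simulate_water(span_start, span_end, seeds[2L])
  height_min <- if (cfg$water_effect != 1) {
    stats::approx(as.numeric(water$timestamp), water$height_cm,
                  xout = as.numeric(t), rule = 2)$y
  } else NULL

  lam <- intensity_core(t, cfg, sunrise, sunset, height_min)
  set.seed(seeds[1L])
  if (cfg$period_sd > 0) {
    per <- segment_light_periods(span_start, span_end, cfg$site)
    pidx <- findInterval(as.numeric(t), as.numeric(per$start))
    eff <- exp(stats::rnorm(nrow(per), 0, cfg$period_sd) - cfg$period_sd^2 / 2)
    lam <- lam * eff[pmax(pidx, 1L)]
  }
  if (cfg$bout_sd > 0) {
    lam <- lam * bout_modulation(length(lam), cfg$bout_sd, cfg$bout_tau_h)
  }
  counts <- if (is.finite(cfg$dispersion)) {
    stats::rnbinom(length(lam), size = cfg$dispersion, mu = lam)
  } else {
    stats::rpois(length(lam), lam)
  }

  sched <- if (is.null(cfg$gap_schedule)) {
    default_gap_schedule(cfg, span_start, span_end, seeds[3L])
  } else cfg$gap_schedule
  keep <- rep(TRUE, length(t))
  dl <- sched$log
  ret <- dl$timestamp[dl$kind == "retrieval"]
  dep <- dl$timestamp[dl$kind == "deployment"]
  redeploy <- dep[dep > span_start]
  for (j in seq_along(ret)) {  # logger out of the water between events
    keep <- keep & !(t >= ret[j] & (j > length(redeploy) | t < redeploy[j]))
  }
  for (j in seq_len(nrow(sched$outages))) {
    keep <- keep & !(t >= sched$outages$start[j] & t < sched$outages$end[j])
  }

  clicks <- click_series(t[keep], counts[keep],
                         span_start = span_start, span_end = span_end)
  mr <- mean_resultant(time_to_angle(t), lam)
  night <- !(as.numeric(t) >= as.numeric(sunrise) &
               as.numeric(t) < as.numeric(sunset))
  truth <- list(
    config = cfg,
    true_peak_angle = mr$mu,
    true_peak_clock = angle_to_clock(mr$mu, utc_offset = cfg$site$utc_offset),
    day_night_median_contrast = stats::median(lam[night]) -
      stats::median(lam[!night]))
  structure(list(clicks = clicks, water = water, deployments = sched$log,
                 truth = truth, config = cfg),
            class = "synthetic_dataset")
}

# mean-one lognormal AR(1) bout modulation, drawn on a 30-min grid and
# linearly interpolated to minutes (uses the current RNG stream)
bout_modulation <- function(n_minutes, bout_sd, bout_tau_h) {
  step <- 30
  n_grid <- ceiling(n_minutes / step) + 1L
  phi <- exp(-step / (bout_tau_h * 60))
  innov <- stats::rnorm(n_grid, 0, bout_sd * sqrt(1 - phi^2))
  innov[1L] <- stats::rnorm(1, 0, bout_sd)
  b <- as.numeric(stats::filter(innov, phi, method = "recursive",
                                init = 0))
  grid_min <- (seq_len(n_grid) - 1L) * step
  e <- stats::approx(grid_min, b, xout = seq_len(n_minutes) - 1L)$y
  exp(e - bout_sd^2 / 2)
}

# tide-like water level on a 10-min grid: M2 + S2 harmonics, the M2
# amplitude weakly modulated over the spring/neap (synodic) cycle, plus a
# heavy-tailed AR(1) surge (wind-driven, dominant in the emulated waters)
simulate_water <- function(span_start, span_end, seed) {
  set.seed(seed)
  tt <- seq(as.numeric(span_start), as.numeric(span_end), by = 600)
  hrs <- tt / 3600
  spring_neap <- 1 + 0.15 * cos(2 * lunar_info(
    as.POSIXct(tt, origin = "1970-01-01", tz = "UTC"))$phase_angle)
  tide <- 14 * spring_neap * sin(2 * pi * hrs / 12.4206012) +
    5 * sin(2 * pi * hrs / 12 + 1)
  innov <- 1.5 * stats::rt(length(tt), df = 4)
  surge <- stats::filter(innov, 0.99, method = "recursive")
  water_level(as.POSIXct(tt, origin = "1970-01-01", tz = "UTC"),
              round(tide + as.numeric(surge), 1))
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic dataset: %d days from %s (seed %d)>\n",
              x$config$n_days, format(x$config$start_date), x$config$seed))
  print(x$clicks)
  invisible(x)
}

#' Write a preset synthetic dataset to disk
#'
#' Writes `clicks.csv`, `waterlevel.csv`, `deployments.csv` and
#' `truth.json` (the full generating config plus derived truth) under
#' `dir`.
#'
#' @param name preset id (see [preset_config()]).
#' @param dir output directory (created if needed).
#' @param seed optional master-seed override.
#' @return the directory path, invisibly.
#' @export
make_fixture <- function(name, dir, seed = NULL) {
  cfg <- preset_config(name, seed = seed)
  d <- simulate_dataset(cfg)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_click_minutes(d$clicks, file.path(dir, "clicks.csv"))
  write_water_level(d$water, file.path(dir, "waterlevel.csv"))
  write_deployment_log(d$deployments, file.path(dir, "deployments.csv"))
  tr <- d$truth
  tr$config <- unclass(tr$config)
  tr$config$site <- unclass(tr$config$site)
  tr$config$start_date <- format(tr$config$start_date)
  tr$config$gap_schedule <- NULL
  jsonlite::write_json(tr, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
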