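# End-to-end analysis: trim -> segment -> summarise -> covariates ->
# randomisation tests (day/night, crepuscular, lunar pairwise, water) ->
# circular fit and Rayleigh test -> report. Stage order is fixed and every
# stochastic step draws its own sub-seed from the master seed, so a report
# is reproducible bit-for-bit from its configuration.

#' Analysis configuration
#'
#' @param site a [site()]; default Kerteminde harbour (55.45 N, 10.66 E,
#'   UTC+2).
#' @param B randomisation replicates (default 5000).
#' @param alpha nominal significance level recorded in the report.
#' @param crepuscular_window_h crepuscular window width in hours (default 2:
#'   2 h before sunrise and 2 h after sunset).
#' @param crepuscular_unit unit of observation for the crepuscular test:
#'   `"daily_median"` (default: one median per local date and label) or
#'   `"minute"` (per-minute counts pooled over the record). The daily-median
#'   unit is the default because the sample median of some 1e5 pooled count
#'   minutes is numerically rigid — under any null both group medians
#'   collapse to the same integer and the test degenerates to p = 1 — while
#'   daily medians vary between dates and keep the statistic informative.
#' @param water_split_cm low/high tide boundary (default 28 cm; the split
#'   value falls in the high group).
#' @param max_missing_minutes completeness tolerance per period (default 0).
#' @param neff_mode effective-sample-size convention for the weighted
#'   circular statistics (see [rayleigh_test()]).
#' @param zenith_deg solar zenith for sunrise/sunset.
#' @param master_seed master seed for all randomisation tests.
#' @return list of class `"analysis_config"`.
#' @export
analysis_config <- function(site = NULL, B = 5000, alpha = 0.05,
                            crepuscular_window_h = 2,
                            crepuscular_unit = c("daily_median", "minute"),
                            water_split_cm = 28, max_missing_minutes = 0,
                            neff_mode = "weights", zenith_deg = 90.833,
                            master_seed = 1) {
  if (is.null(site)) site <- kerteminde()
  stopifnot(inherits(site, "pam_site"), B >= 1, crepuscular_window_h > 0)
  structure(list(site = site, B = as.integer(B), alpha = alpha,
                 crepuscular_window_h = crepuscular_window_h,
                 crepuscular_unit = match.arg(crepuscular_unit),
                 water_split_cm = water_split_cm,
                 max_missing_minutes = max_missing_minutes,
                 neff_mode = neff_mode, zenith_deg = zenith_deg,
                 master_seed = as.integer(master_seed)),
            class = "analysis_config")
}

#' Run the full diel-activity analysis
#'
#' @param clicks a [click_series()] or path to a click-minute CSV.
#' @param water a `"water_level"` series, path, or `NULL` (the water-level
#'   test is then skipped with a warning; nothing else changes).
#' @param deployments a [deployment_log()], path, or `NULL` (no edge
#'   trimming).
#' @param config an [analysis_config()].
#' @param verbose log record counts per stage.
#' @return object of class `"analysis_report"`: `periods` (per-period
#'   summaries with covariates), `tests` (named list: `day_night`,
#'   `crepuscular`, `lunar` — pairwise, `water`), `rayleigh`,
#'   `circular_fit`, `peak_clock` (local clock time with CI),
#'   `hour_month_median` (24 x 12 matrix), `provenance` (config, seeds,
#'   package version).
#' @export
run_analysis <- function(clicks, water = NULL, deployments = NULL,
                         config = analysis_config(), verbose = FALSE) {
  stopifnot(inherits(config, "analysis_config"))
  if (is.character(clicks)) clicks <- read_click_minutes(clicks)
  if (is.character(water)) water <- read_water_level(water)
  if (is.character(deployments)) deployments <- read_deployment_log(deployments)
  stopifnot(inherits(clicks, "click_series"))
  if (as.numeric(clicks$span_end - clicks$span_start, units = "days") < 14) {
    stop("record span must be at least 14 days for the circular fit")
  }
  say <- function(...) if (verbose) message(sprintf(...))
  say("input: %d recorded minutes", nrow(clicks$records))

  set.seed(config$master_seed)
  seeds <- sample.int(.Machine$integer.max, 4L)
  names(seeds) <- c("day_night", "crepuscular", "lunar", "water")

  if (!is.null(deployments)) {
    clicks <- trim_deployment_edges(clicks, deployments)
    say("after edge trimming: %d recorded minutes", nrow(clicks$records))
  }

  periods <- segment_light_periods(clicks$span_start, clicks$span_end,
                                   config$site, config$zenith_deg)
  summaries <- summarise_periods(clicks, periods,
                                 config$max_missing_minutes)
  summaries <- attach_night_covariates(summaries, water,
                                       config$site, config$water_split_cm)
  comp <- summaries[summaries$complete, , drop = FALSE]
  say("periods: %d total, %d complete (%d day, %d night)",
      nrow(summaries), nrow(comp), sum(comp$kind == "day"),
      sum(comp$kind == "night"))
  if (nrow(comp) == 0L) {
    stop("no complete periods survive the complete-data filter ",
         "(max_missing_minutes = ", config$max_missing_minutes, ")")
  }

  tests <- list()
  day_med <- comp$median_cpm[comp$kind == "day"]
  night_med <- comp$median_cpm[comp$kind == "night"]
  tests$day_night <- if (length(day_med) && length(night_med)) {
    randomisation_test(night_med, day_med, B = config$B,
                       seed = seeds[["day_night"]])
  } else NULL

  tests$crepuscular <- crepuscular_test(clicks, config,
                                        seed = seeds[["crepuscular"]])

  night_rows <- comp[comp$kind == "night", , drop = FALSE]
  tests$lunar <- if (nrow(night_rows) >= 2L &&
                     nlevels(droplevels(night_rows$lunar_phase)) >= 2L) {
    pairwise_randomisation(night_rows$median_cpm, night_rows$lunar_phase,
                           B = config$B, seed = seeds[["lunar"]])
  } else NULL

  if (is.null(water)) {
    warning("no water-level series: water test skipped")
    tests$water <- NULL
  } else {
    wok <- !is.na(night_rows$water_group)
    lo <- night_rows$median_cpm[wok & night_rows$water_group == "low"]
    hi <- night_rows$median_cpm[wok & night_rows$water_group == "high"]
    tests$water <- if (length(lo) && length(hi)) {
      randomisation_test(lo, hi, B = config$B, seed = seeds[["water"]])
    } else NULL
  }

  ang <- time_to_angle(clicks$records$timestamp)
  w <- clicks$records$clicks
  rayleigh <- rayleigh_test(ang, w, neff_mode = config$neff_mode)
  fit <- fit_vonmises(ang, w, neff_mode = config$neff_mode)
  peak_clock <- angle_to_clock(fit$mu, fit$ci_mu,
                               utc_offset = config$site$utc_offset)

  hm <- hour_month_matrix(clicks, utc_offset = config$site$utc_offset)

  structure(list(periods = summaries, tests = tests, rayleigh = rayleigh,
                 circular_fit = fit, peak_clock = peak_clock,
                 hour_month_median = hm,
                 provenance = list(config = config, seeds = seeds,
                                   package_version =
                                     as.character(utils::packageVersion("dielPAM")))),
            class = "analysis_report")
}

#' Crepuscular vs other-times randomisation test
#'
#' Compares click counts in crepuscular minutes (within
#' `crepuscular_window_h` before sunrise / after sunset) against all other
#' recorded minutes. With `crepuscular_unit = "minute"` the unit of
#' observation is the minute count pooled over the record; with
#' `"daily_median"` it is the median per local date and label.
#'
#' @param clicks a [click_series()].
#' @param config an [analysis_config()].
#' @param seed integer seed.
#' @return a `"randomisation_result"`.
#' @export
crepuscular_test <- function(clicks, config = analysis_config(),
                             seed = NULL) {
  stopifnot(inherits(clicks, "click_series"))
  lab <- label_crepuscular(clicks$records$timestamp, config$site,
                           config$crepuscular_window_h, config$zenith_deg)
  if (!any(lab) || all(lab)) {
    stop("crepuscular labelling produced an empty group ",
         "(window ", config$crepuscular_window_h, " h)")
  }
  if (config$crepuscular_unit == "minute") {
    randomisation_test(clicks$records$clicks[lab],
                       clicks$records$clicks[!lab],
                       B = config$B, seed = seed)
  } else {
    day_key <- local_date(clicks$records$timestamp, config$site$utc_offset)
    med <- function(keep) {
      as.numeric(tapply(clicks$records$clicks[keep], day_key[keep],
                        stats::median))
    }
    randomisation_test(med(lab), med(!lab), B = config$B, seed = seed)
  }
}

#' Hour-of-day by month matrix of median clicks per minute
#'
#' Cell (h, m) is the median over all recorded minutes falling in local
#' hour h of calendar month m. Gap minutes are excluded; empty cells are
#' `NA`, never zero.
#'
#' @param clicks a [click_series()].
#' @param utc_offset hours; local time uses this fixed offset.
#' @return 24 x 12 numeric matrix, rows `"00".."23"`, columns
#'   `"Jan".."Dec"`.
#' @export
hour_month_matrix <- function(clicks, utc_offset = 0) {
  stopifnot(inherits(clicks, "click_series"))
  tloc <- as.numeric(clicks$records$timestamp) + utc_offset * 3600
  hour <- (tloc %/% 3600) %% 24
  month <- as.integer(format(as.POSIXct(tloc, origin = "1970-01-01",
                                        tz = "UTC"), "%m"))
  out <- matrix(NA_real_, 24, 12,
                dimnames = list(sprintf("%02d", 0:23), month.abb))
  agg <- tapply(clicks$records$clicks,
                list(factor(hour, levels = 0:23),
                     factor(month, levels = 1:12)),
                stats::median)
  out[] <- agg
  out
}

#' @export
print.analysis_report <- function(x, ...) {
  comp <- x$periods[x$periods$complete, ]
  cat("Diel activity analysis report\n")
  cat(sprintf("  complete periods: %d (%d day, %d night)\n", nrow(comp),
              sum(comp$kind == "day"), sum(comp$kind == "night")))
  fmtp <- function(p, a = 0.01) if (p < a) sprintf("< %.2g", a) else sprintf("= %.3f", p)
  if (!is.null(x$tests$day_night)) {
    cat(sprintf("  day/night:   median diff %.2f clicks/min, p %s\n",
                x$tests$day_night$observed, fmtp(x$tests$day_night$p_value)))
  }
  if (!is.null(x$tests$crepuscular)) {
    cat(sprintf("  crepuscular: median diff %.2f clicks/min, p %s\n",
                x$tests$crepuscular$observed, fmtp(x$tests$crepuscular$p_value)))
  }
  if (!is.null(x$tests$lunar)) {
    pr <- range(vapply(x$tests$lunar, function(r) r$p_value, numeric(1)))
    cat(sprintf("  lunar phase: pairwise p-values %.3f .. %.3f (uncorrected)\n",
                pr[1], pr[2]))
  }
  if (!is.null(x$tests$water)) {
    cat(sprintf("  water level: median diff %.2f clicks/min, p %s\n",
                x$tests$water$observed, fmtp(x$tests$water$p_value)))
  }
  cat(sprintf("  Rayleigh: r_bar = %.3f, p %s (n_eff = %.0f)\n",
              x$rayleigh$r_bar, fmtp(x$rayleigh$p_value), x$rayleigh$n_eff))
  cat(sprintf("  peak clicking time: %s local (%d%% CI %s - %s)\n",
              x$peak_clock[["time"]],
              round(100 * x$circular_fit$conf),
              x$peak_clock[["ci_lower"]], x$peak_clock[["ci_upper"]]))
  invisible(x)
}

#' Write an analysis report as machine-readable tables
#'
#' Writes `periods.csv` (per-period summaries), `tests.csv` (one row per
#' hypothesis test with statistic, p, replicate count and the seed that
#' regenerates its null exactly), `circular_fit.csv` and
#' `hour_month_median.csv` (24 x 12) under `dir`. Output is deterministic:
#' rerunning the same analysis writes byte-identical files.
#'
#' @param report an `"analysis_report"`.
#' @param dir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)

  p <- report$periods
  pv <- data.frame(period_start = format_utc(p$start),
                   period_end = format_utc(p$end),
                   kind = p$kind, complete = p$complete,
                   median_cpm = p$median_cpm,
                   lunar_phase = as.character(p$lunar_phase),
                   illum_bin = p$illum_bin,
                   water_group = as.character(p$water_group))
  f <- file.path(dir, "periods.csv")
  utils::write.csv(pv, f, row.names = FALSE, quote = FALSE, na = "")
  paths <- c(paths, f)

  row1 <- function(name, ga, gb, r) {
    data.frame(test_name = name, group_a = ga, group_b = gb,
               n_a = r$n_a, n_b = r$n_b, observed = r$observed,
               p_value = r$p_value, B = r$B,
               seed = if (is.null(r$seed)) NA_integer_ else r$seed)
  }
  rows <- list()
  if (!is.null(report$tests$day_night)) {
    rows <- c(rows, list(row1("day_night", "night", "day",
                              report$tests$day_night)))
  }
  if (!is.null(report$tests$crepuscular)) {
    rows <- c(rows, list(row1("crepuscular", "crepuscular", "other",
                              report$tests$crepuscular)))
  }
  if (!is.null(report$tests$lunar)) {
    lt <- as.data.frame(report$tests$lunar)
    rows <- c(rows, list(cbind(test_name = paste0("lunar_", lt$group_a, "_",
                                                  lt$group_b), lt)))
  }
  if (!is.null(report$tests$water)) {
    rows <- c(rows, list(row1("water", "low", "high", report$tests$water)))
  }
  f <- file.path(dir, "tests.csv")
  utils::write.csv(do.call(rbind, rows), f, row.names = FALSE, quote = FALSE)
  paths <- c(paths, f)

  fit <- report$circular_fit
  cf <- data.frame(mu_rad = fit$mu, mu_clock = report$peak_clock[["time"]],
                   kappa = fit$kappa, r_bar = fit$r_bar, n_eff = fit$n_eff,
                   ci_lower_clock = report$peak_clock[["ci_lower"]],
                   ci_upper_clock = report$peak_clock[["ci_upper"]],
                   rayleigh_stat = report$rayleigh$r_bar,
                   rayleigh_p = report$rayleigh$p_value,
                   neff_mode = fit$neff_mode)
  f <- file.path(dir, "circular_fit.csv")
  utils::write.csv(cf, f, row.names = FALSE, quote = FALSE)
  paths <- c(paths, f)

  f <- file.path(dir, "hour_month_median.csv")
  utils::write.csv(as.data.frame(report$hour_month_median), f,
                   row.names = TRUE, quote = FALSE, na = "")
  paths <- c(paths, f)
  invisible(paths)
}
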