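# Preprocessing: deployment-edge trimming, light/dark segmentation,
# per-period medians, crepuscular labelling, covariate discretisation.
# Interval convention is half-open [start, end) throughout, so consecutive
# periods tile time exactly and boundary minutes are never double-counted.

#' Trim minutes around deployment and retrieval events
#'
#' Removes the 5 minutes from each deployment (`[t, t + 5 min)`, logger
#' settling and immediate biosonar inspection) and the 2 minutes before each
#' retrieval (`[t - 2 min, t)`). Removed minutes become gaps; the declared
#' span is unchanged, so the operation is idempotent.
#'
#' @param series a [click_series()].
#' @param log a [deployment_log()] (may have zero rows).
#' @param post_deployment_min,pre_retrieval_min window widths in minutes.
#' @return the trimmed [click_series()].
#' @export
trim_deployment_edges <- function(series, log,
                                  post_deployment_min = 5,
                                  pre_retrieval_min = 2) {
  stopifnot(inherits(series, "click_series"), inherits(log, "deployment_log"))
  if (nrow(log) == 0L) return(series)
  dep <- log$timestamp[log$kind == "deployment"]
  ret <- log$timestamp[log$kind == "retrieval"]
  starts <- c(dep, ret - pre_retrieval_min * MINUTE)
  ends <- c(dep + post_deployment_min * MINUTE, ret)
  drop_minutes(series, starts, ends)
}

#' Segment a time span into alternating light and dark periods
#'
#' Day periods run sunrise to sunset; night periods run sunset to the next
#' sunrise. Together they tile the span; periods clipped by the span edges
#' are flagged `partial` and excluded from downstream tests.
#'
#' @param span_start,span_end UTC timestamps bounding the analysed span
#'   (half-open), at least one day apart.
#' @param site a [site()].
#' @param zenith_deg solar zenith for the events (see [solar_events()]).
#' @return data.frame with `kind` ("day"/"night"), `start`, `end` (`POSIXct`
#'   UTC, clipped to the span), `date_key` (local civil date of the period's
#'   natural start) and `partial` (logical).
#' @export
segment_light_periods <- function(span_start, span_end, site,
                                  zenith_deg = 90.833) {
  span_start <- parse_utc(span_start)
  span_end <- parse_utc(span_end)
  if (as.numeric(span_end - span_start, units = "days") < 1) {
    stop("span must cover at least one day")
  }
  d0 <- local_date(span_start, site$utc_offset) - 1
  d1 <- local_date(span_end, site$utc_offset) + 1
  ev <- solar_events(seq(d0, d1, by = "day"), site, zenith_deg)
  if (anyNA(ev$sunrise)) {
    stop("polar day/night within the span: no sunrise/sunset event exists")
  }
  n <- nrow(ev)
  as_ct <- function(x) as.POSIXct(x, origin = "1970-01-01", tz = "UTC")
  starts <- as_ct(c(rbind(ev$sunrise, ev$sunset)))           # sr1 ss1 sr2 ...
  ends <- as_ct(c(rbind(ev$sunset, c(ev$sunrise[-1L], NA)))) # ss1 sr2 ss2 ...
  kind <- rep(c("day", "night"), n)
  date_key <- rep(ev$date, each = 2L)
  ok <- !is.na(ends)
  starts <- starts[ok]; ends <- ends[ok]; kind <- kind[ok]
  date_key <- date_key[ok]
  keep <- ends > span_start & starts < span_end
  starts <- starts[keep]; ends <- ends[keep]; kind <- kind[keep]
  date_key <- date_key[keep]
  partial <- starts < span_start | ends > span_end
  out <- data.frame(
    kind = kind,
    start = pmax(starts, span_start),
    end = pmin(ends, span_end),
    date_key = date_key,
    partial = partial)
  attr(out$start, "tzone") <- "UTC"
  attr(out$end, "tzone") <- "UTC"
  out
}

#' Summarise click activity per light/dark period
#'
#' Computes the median clicks per minute within each period. A period is
#' `complete` when every one of its minutes has a record (up to
#' `max_missing_minutes`), it is not partial, and it lies inside the series'
#' declared span; only complete periods enter the randomisation tests.
#'
#' @param series a [click_series()].
#' @param periods output of [segment_light_periods()].
#' @param max_missing_minutes tolerated missing minutes per period before it
#'   is declared incomplete (default 0: one missing minute excludes).
#' @return `periods` with added columns `n_minutes` (expected), `n_recorded`,
#'   `complete` and `median_cpm` (`NA` when incomplete).
#' @export
summarise_periods <- function(series, periods, max_missing_minutes = 0) {
  stopifnot(inherits(series, "click_series"))
  t <- as.numeric(series$records$timestamp)
  ps <- as.numeric(periods$start)
  pe <- as.numeric(periods$end)
  expected <- floor(pe / MINUTE) - ceiling(ps / MINUTE) +
    (pe %% MINUTE > 0)  # minutes whose start lies in [start, end)
  # assign each record to the period containing it (periods tile the span)
  idx <- findInterval(t, ps)
  idx[idx >= 1L & t >= pe[pmax(idx, 1L)]] <- 0L
  valid <- idx >= 1L
  n_rec <- tabulate(idx[valid], nbins = nrow(periods))
  med <- rep(NA_real_, nrow(periods))
  sp <- split(series$records$clicks[valid], idx[valid])
  med[as.integer(names(sp))] <- vapply(sp, stats::median, numeric(1))
  inside <- ps >= as.numeric(series$span_start) &
    pe <= as.numeric(series$span_end)
  complete <- !periods$partial & inside &
    (expected - n_rec) <= max_missing_minutes & n_rec > 0L
  out <- periods
  out$n_minutes <- as.integer(expected)
  out$n_recorded <- n_rec
  out$complete <- complete
  out$median_cpm <- ifelse(complete, med, NA_real_)
  out
}

#' Label crepuscular minutes
#'
#' A timestamp is crepuscular when it falls within `window_h` hours before
#' sunrise (`[sunrise - w, sunrise)`) or after sunset
#' (`[sunset, sunset + w)`).
#'
#' @param t timestamp vector (`POSIXct` UTC or parseable).
#' @param site a [site()].
#' @param window_h window width in hours (default 2).
#' @param zenith_deg solar zenith for the events.
#' @return logical vector.
#' @export
label_crepuscular <- function(t, site, window_h = 2, zenith_deg = 90.833) {
  t <- parse_utc(t)
  stopifnot(window_h > 0)
  dr <- range(local_date(t, site$utc_offset))
  ev <- solar_events(seq(dr[1L] - 1, dr[2L] + 1, by = "day"), site, zenith_deg)
  w <- window_h * 3600
  starts <- sort(c(as.numeric(ev$sunrise) - w, as.numeric(ev$sunset)))
  ends <- sort(c(as.numeric(ev$sunrise), as.numeric(ev$sunset) + w))
  i <- findInterval(as.numeric(t), starts)
  i >= 1L & as.numeric(t) < ends[pmax(i, 1L)]
}

#' Discretise lunar illumination into quartile bins
#'
#' Equally spaced bins \[0, 0.25), \[0.25, 0.5), \[0.5, 0.75), \[0.75, 1\]
#' (the last bin closed at 1).
#'
#' @param f illuminated fraction in \[0, 1\].
#' @return integer bin 1-4.
#' @export
discretise_illumination <- function(f) {
  if (any(f < 0 | f > 1, na.rm = TRUE)) {
    stop("illumination must lie in [0, 1]")
  }
  b <- findInterval(f, c(0, 0.25, 0.5, 0.75))
  b[f == 1] <- 4L
  b
}

#' Discretise water level into low/high tide groups
#'
#' Heights below `split_cm` are "low", heights at or above it are "high"
#' (the split value itself is the lower bound of the high group).
#'
#' @param height_cm numeric heights (cm relative to local mean sea level).
#' @param split_cm group boundary (default 28 cm).
#' @return factor with levels low, high (`NA` preserved).
#' @export
discretise_water <- function(height_cm, split_cm = 28) {
  factor(ifelse(height_cm < split_cm, "low", "high"),
         levels = c("low", "high"))
}

#' Attach night-time covariates to period summaries
#'
#' For each night period: lunar phase category and illumination bin are
#' evaluated at the dark-period midpoint; the water-level group is the
#' [discretise_water()] of the median water height over the period. Nights
#' without any water sample get `NA` and drop out of the water-level test
#' only.
#'
#' @param summaries output of [summarise_periods()].
#' @param water a `"water_level"` data.frame, or `NULL` to skip water.
#' @param site a [site()] (unused for lunar timing, kept for interface
#'   symmetry and future site-dependent covariates).
#' @param split_cm water split passed to [discretise_water()].
#' @return `summaries` with added `lunar_phase`, `illum_bin`, `water_group`
#'   (all `NA` for day periods).
#' @export
attach_night_covariates <- function(summaries, water = NULL, site = NULL,
                                    split_cm = 28) {
  n <- nrow(summaries)
  out <- summaries
  out$lunar_phase <- factor(rep(NA_character_, n),
                            levels = c("new", "waxing", "full", "waning"))
  out$illum_bin <- rep(NA_integer_, n)
  out$water_group <- factor(rep(NA_character_, n), levels = c("low", "high"))
  night <- summaries$kind == "night"
  if (any(night)) {
    mid <- summaries$start[night] +
      as.numeric(summaries$end[night] - summaries$start[night],
                 units = "secs") / 2
    li <- lunar_info(mid)
    out$lunar_phase[night] <- li$phase_category
    out$illum_bin[night] <- discretise_illumination(li$illumination)
    if (!is.null(water)) {
      wt <- as.numeric(water$timestamp)
      med_h <- mapply(function(s, e) {
        h <- water$height_cm[wt >= s & wt < e]
        if (length(h) == 0L) NA_real_ else stats::median(h)
      }, as.numeric(summaries$start[night]), as.numeric(summaries$end[night]))
      out$water_group[night] <- discretise_water(med_h, split_cm)
    }
  }
  out
}
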