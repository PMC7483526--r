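# Containers for minute-resolution click records and their gap structure.
# Absent minutes within the declared span are gaps (unknown), never zeros:
# quiet minutes must carry an explicit 0, matching the distinction between
# silence and a logger out of the water.

#' Construct a click-minute series
#'
#' @param timestamp `POSIXct` UTC (or parseable) minute timestamps, strictly
#'   increasing, on whole minutes.
#' @param clicks non-negative integer clicks detected in each minute.
#' @param span_start,span_end declared span of the record (half-open
#'   `[span_start, span_end)`); defaults to the recorded extent. Minutes of
#'   the span with no record become gap intervals.
#' @return An object of class `"click_series"`: a list with `records`
#'   (data.frame `timestamp`, `clicks`), `span_start`, `span_end` and `gaps`
#'   (data.frame of half-open `start`/`end` intervals).
#' @export
click_series <- function(timestamp, clicks, span_start = NULL, span_end = NULL) {
  timestamp <- parse_utc(timestamp)
  if (length(timestamp) == 0L) stop("empty series: no click records")
  if (length(timestamp) != length(clicks)) {
    stop("timestamp and clicks lengths differ")
  }
  if (!all(is_whole_minute(timestamp))) {
    bad <- which(!is_whole_minute(timestamp))[1L]
    stop("timestamp not on a whole minute (row ", bad, ")")
  }
  if (anyNA(clicks) || any(clicks < 0) || any(clicks != as.integer(clicks))) {
    bad <- which(is.na(clicks) | clicks < 0 | clicks != as.integer(clicks))[1L]
    stop("clicks must be non-negative integers (row ", bad, ")")
  }
  d <- diff(as.numeric(timestamp))
  if (any(d == 0)) {
    stop("duplicate minute at row ", which(d == 0)[1L] + 1L)
  }
  if (any(d < 0)) {
    stop("timestamps not in increasing order at row ", which(d < 0)[1L] + 1L)
  }
  span_start <- if (is.null(span_start)) timestamp[1L] else parse_utc(span_start)
  span_end <- if (is.null(span_end)) timestamp[length(timestamp)] + MINUTE else parse_utc(span_end)
  if (span_start > timestamp[1L] || span_end < timestamp[length(timestamp)] + MINUTE) {
    stop("declared span does not cover the records")
  }
  obj <- structure(list(
    records = data.frame(timestamp = timestamp, clicks = as.integer(clicks)),
    span_start = span_start, span_end = span_end,
    gaps = NULL), class = "click_series")
  obj$gaps <- compute_gaps(obj)
  obj
}

# half-open gap intervals: span minutes with no record
compute_gaps <- function(x) {
  m <- as.numeric(x$records$timestamp) / MINUTE
  m0 <- as.numeric(x$span_start) / MINUTE
  m1 <- as.numeric(x$span_end) / MINUTE
  present <- logical(m1 - m0)
  present[m - m0 + 1L] <- TRUE
  r <- rle(present)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- !r$values
  data.frame(
    start = as.POSIXct((m0 + starts[keep] - 1L) * MINUTE,
                       origin = "1970-01-01", tz = "UTC"),
    end = as.POSIXct((m0 + ends[keep]) * MINUTE,
                     origin = "1970-01-01", tz = "UTC"))
}

#' @export
print.click_series <- function(x, ...) {
  gap_min <- if (nrow(x$gaps)) sum(as.numeric(x$gaps$end - x$gaps$start,
                                              units = "mins")) else 0
  cat(sprintf("<click_series: %d recorded minutes, %s .. %s, %d gap interval(s) (%.0f min)>\n",
              nrow(x$records), format_utc(x$span_start), format_utc(x$span_end),
              nrow(x$gaps), gap_min))
  invisible(x)
}

#' @export
summary.click_series <- function(object, ...) {
  c(minutes = nrow(object$records),
    total_clicks = sum(object$records$clicks),
    median_cpm = stats::median(object$records$clicks),
    gap_minutes = as.integer(span_minutes(object) - nrow(object$records)))
}

span_minutes <- function(x) {
  as.integer(as.numeric(x$span_end - x$span_start, units = "mins"))
}

# drop the records whose minute falls in any half-open [starts, ends) window;
# the declared span is kept, so dropped minutes become gaps
drop_minutes <- function(x, starts, ends) {
  if (length(starts) == 0L) return(x)
  t <- as.numeric(x$records$timestamp)
  drop <- rep(FALSE, length(t))
  for (i in seq_along(starts)) {
    drop <- drop | (t >= as.numeric(starts[i]) & t < as.numeric(ends[i]))
  }
  if (!any(drop)) return(x)
  if (all(drop)) stop("trimming removed every record in the series")
  x$records <- x$records[!drop, , drop = FALSE]
  rownames(x$records) <- NULL
  x$gaps <- compute_gaps(x)
  x
}
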