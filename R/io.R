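# File formats. The canonical dialect for every input is comma-separated
# UTF-8 with a header row and ISO-8601 UTC timestamps; ingestion starts at
# the exported click-minute table (the proprietary logger formats are not
# parsed). All writers round-trip losslessly through the readers.

#' Read a click-minute CSV
#'
#' Expects columns `timestamp` (ISO-8601 UTC, whole minutes) and `clicks`
#' (non-negative integer). Minutes absent from the file within its span are
#' recorded as gaps, not zeros.
#'
#' @param path CSV file path.
#' @param span_start,span_end optional declared span overriding the recorded
#'   extent (see [click_series()]).
#' @return a [click_series()].
#' @export
read_click_minutes <- function(path, span_start = NULL, span_end = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "clicks")
  if (!all(need %in% names(d))) {
    stop("click file must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(d) == 0L) stop("empty series: no click records in ", path)
  if (!is.numeric(d$clicks)) {
    bad <- which(is.na(suppressWarnings(as.numeric(d$clicks))))[1L]
    stop("non-numeric clicks value (row ", bad, ")")
  }
  click_series(parse_utc(d$timestamp), d$clicks,
               span_start = span_start, span_end = span_end)
}

#' Write a click-minute CSV
#' @param series a [click_series()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_click_minutes <- function(series, path) {
  stopifnot(inherits(series, "click_series"))
  utils::write.csv(
    data.frame(timestamp = format_utc(series$records$timestamp),
               clicks = series$records$clicks),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a water-level CSV
#'
#' Expects columns `timestamp` and `height_cm` (numeric, relative to local
#' mean sea level; negative values are valid).
#'
#' @param path CSV file path.
#' @return data.frame of class `"water_level"` with `timestamp` (`POSIXct`
#'   UTC, strictly increasing) and `height_cm`.
#' @export
read_water_level <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "height_cm")
  if (!all(need %in% names(d))) {
    stop("water-level file must have columns: ", paste(need, collapse = ", "))
  }
  h <- suppressWarnings(as.numeric(d$height_cm))
  if (anyNA(h)) {
    stop("non-numeric height_cm value (row ", which(is.na(h))[1L], ")")
  }
  water_level(parse_utc(d$timestamp), h)
}

#' Construct a water-level series
#' @param timestamp `POSIXct` UTC (or parseable), strictly increasing.
#' @param height_cm numeric heights in cm relative to local mean sea level.
#' @return data.frame of class `"water_level"`.
#' @export
water_level <- function(timestamp, height_cm) {
  timestamp <- parse_utc(timestamp)
  stopifnot(length(timestamp) == length(height_cm))
  d <- diff(as.numeric(timestamp))
  if (any(d <= 0)) {
    stop("water-level timestamps not strictly increasing at row ",
         which(d <= 0)[1L] + 1L)
  }
  structure(data.frame(timestamp = timestamp, height_cm = as.numeric(height_cm)),
            class = c("water_level", "data.frame"))
}

#' Write a water-level CSV
#' @param water a `"water_level"` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_water_level <- function(water, path) {
  utils::write.csv(
    data.frame(timestamp = format_utc(water$timestamp),
               height_cm = water$height_cm),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a deployment-event log
#'
#' Expects columns `timestamp` and `kind` (`deployment` or `retrieval`).
#' Events must alternate, starting with a deployment.
#'
#' @param path CSV file path.
#' @return data.frame of class `"deployment_log"`.
#' @export
read_deployment_log <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "kind")
  if (!all(need %in% names(d))) {
    stop("deployment log must have columns: ", paste(need, collapse = ", "))
  }
  deployment_log(parse_utc(d$timestamp), d$kind)
}

#' Construct a deployment-event log
#' @param timestamp event times (`POSIXct` UTC or parseable), increasing.
#' @param kind character, `"deployment"` or `"retrieval"`, alternating and
#'   starting with a deployment.
#' @return data.frame of class `"deployment_log"`.
#' @export
deployment_log <- function(timestamp, kind) {
  timestamp <- parse_utc(timestamp)
  kind <- as.character(kind)
  stopifnot(length(timestamp) == length(kind))
  if (!all(kind %in% c("deployment", "retrieval"))) {
    stop("event kind must be 'deployment' or 'retrieval'")
  }
  if (length(kind) > 0L) {
    if (kind[1L] != "deployment") {
      stop("retrieval before any deployment in the event log")
    }
    expected <- rep_len(c("deployment", "retrieval"), length(kind))
    if (!all(kind == expected)) {
      stop("deployment/retrieval events must alternate (row ",
           which(kind != expected)[1L], ")")
    }
    if (length(timestamp) > 1L && any(diff(as.numeric(timestamp)) <= 0)) {
      stop("event timestamps not strictly increasing")
    }
  }
  structure(data.frame(timestamp = timestamp, kind = kind),
            class = c("deployment_log", "data.frame"))
}

#' Write a deployment-event log CSV
#' @param log a `"deployment_log"` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_deployment_log <- function(log, path) {
  utils::write.csv(
    data.frame(timestamp = format_utc(log$timestamp), kind = log$kind),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
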