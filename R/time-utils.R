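#' @keywords internal
"_PACKAGE"

# Internal time helpers. All timestamps are POSIXct in UTC; local civil time
# enters only through a fixed UTC offset carried by the site (no DST).

MINUTE <- 60
DAY <- 86400

#' Parse timestamps to UTC POSIXct
#'
#' Accepts ISO-8601 strings (`"2016-06-06T12:00:00Z"`, `"2016-06-06 12:00"`,
#' with or without seconds/`Z`), `POSIXct`, or `Date` (taken as 00:00 UTC).
#'
#' @param x character, `POSIXct` or `Date` vector.
#' @return `POSIXct` vector in UTC.
#' @export
parse_utc <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  if (inherits(x, "Date")) {
    return(as.POSIXct(as.numeric(x) * DAY, origin = "1970-01-01", tz = "UTC"))
  }
  x <- as.character(x)
  y <- gsub("T", " ", x, fixed = TRUE)
  y <- sub("Z$", "", y)
  out <- as.POSIXct(y, tz = "UTC",
                    tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M",
                                   "%Y-%m-%d"))
  bad <- is.na(out) & !is.na(x)
  if (any(bad)) {
    stop("unparseable timestamp(s), e.g. '", x[which(bad)[1L]],
         "' (row ", which(bad)[1L], ")")
  }
  out
}

#' Format UTC timestamps as ISO-8601
#' @param t `POSIXct` vector.
#' @return character vector like `"2016-06-06T12:00:00Z"`.
#' @export
format_utc <- function(t) {
  format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

# floor to whole minutes
floor_minute <- function(t) {
  as.POSIXct(floor(as.numeric(t) / MINUTE) * MINUTE,
             origin = "1970-01-01", tz = "UTC")
}

is_whole_minute <- function(t) {
  as.numeric(t) %% MINUTE == 0
}

# local civil date of a UTC timestamp under a fixed offset (hours)
local_date <- function(t, utc_offset) {
  as.Date(floor((as.numeric(t) + utc_offset * 3600) / DAY), origin = "1970-01-01")
}

# minutes since local midnight, in [0, 1440)
local_minute_of_day <- function(t, utc_offset) {
  ((as.numeric(t) + utc_offset * 3600) / MINUTE) %% 1440
}

#' Define a monitoring site
#'
#' A site is a latitude/longitude pair plus a fixed UTC offset used for all
#' local-time labelling (no daylight-saving transitions are applied).
#'
#' @param latitude degrees north, in \[-90, 90\].
#' @param longitude degrees east, in \[-180, 180\].
#' @param utc_offset hours east of UTC, in \[-12, 14\].
#' @return An object of class `"pam_site"`.
#' @examples
#' site(55.45, 10.66, 2)  # Kerteminde harbour, Denmark
#' @export
site <- function(latitude, longitude, utc_offset = 0) {
  stopifnot(is.numeric(latitude), length(latitude) == 1L, is.finite(latitude),
            is.numeric(longitude), length(longitude) == 1L, is.finite(longitude),
            is.numeric(utc_offset), length(utc_offset) == 1L)
  if (latitude < -90 || latitude > 90) stop("latitude must be in [-90, 90]")
  if (longitude < -180 || longitude > 180) stop("longitude must be in [-180, 180]")
  if (utc_offset < -12 || utc_offset > 14) stop("utc_offset must be in [-12, 14]")
  structure(list(latitude = latitude, longitude = longitude,
                 utc_offset = utc_offset),
            class = "pam_site")
}

#' @export
print.pam_site <- function(x, ...) {
  cat(sprintf("<site %.4f%sN %.4f%sE, UTC%+g>\n",
              x$latitude, "°", x$longitude, "°", x$utc_offset))
  invisible(x)
}

# default study site: Kerteminde harbour
kerteminde <- function() site(55.45, 10.66, 2)
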