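# Solar and lunar ephemeris.
#
# Sunrise/sunset come from the standard NOAA solar-position algorithm
# (equation of time + solar declination, refraction-corrected zenith
# 90.833 degrees), accurate to well under a minute at mid latitudes —
# more than enough for 1-minute click bins and 2-h crepuscular windows.
# Lunar phase uses the mean synodic cycle anchored at a published new-moon
# epoch (2000-01-06 18:14 UTC); illumination is (1 - cos(elongation)) / 2.

SYNODIC_DAYS <- 29.530588853
# catalogued new moon, 2000-01-06 18:14 UTC, as Julian day
NEW_MOON_EPOCH_JD <- 2451550.26

# Julian day from UTC POSIXct
jd_from_posix <- function(t) {
  as.numeric(t) / DAY + 2440587.5
}

# NOAA solar geometry at Julian centuries T: declination (deg) and
# equation of time (minutes)
solar_geometry <- function(T) {
  L0 <- (280.46646 + T * (36000.76983 + T * 0.0003032)) %% 360
  M <- 357.52911 + T * (35999.05029 - 0.0001537 * T)
  e <- 0.016708634 - T * (0.000042037 + 0.0000001267 * T)
  Mr <- M * pi / 180
  C <- sin(Mr) * (1.914602 - T * (0.004817 + 0.000014 * T)) +
    sin(2 * Mr) * (0.019993 - 0.000101 * T) +
    sin(3 * Mr) * 0.000289
  omega <- (125.04 - 1934.136 * T) * pi / 180
  app_long <- (L0 + C - 0.00569 - 0.00478 * sin(omega)) * pi / 180
  eps0 <- 23 + (26 + (21.448 - T * (46.815 + T * (0.00059 - T * 0.001813))) / 60) / 60
  eps <- (eps0 + 0.00256 * cos(omega)) * pi / 180
  decl <- asin(sin(eps) * sin(app_long))
  y <- tan(eps / 2)^2
  L0r <- L0 * pi / 180
  eot <- 4 * (180 / pi) * (y * sin(2 * L0r) - 2 * e * sin(Mr) +
    4 * e * y * sin(Mr) * cos(2 * L0r) -
    0.5 * y^2 * sin(4 * L0r) - 1.25 * e^2 * sin(2 * Mr))
  list(declination = decl, eot_min = eot)
}

#' Sunrise and sunset for local civil dates
#'
#' Computes refraction-corrected sunrise and sunset for each requested local
#' civil date at a site, using the NOAA solar-position algorithm. Events are
#' returned as UTC timestamps but belong to the given date in the site's
#' fixed-offset local time.
#'
#' @param dates `Date` vector (or coercible) of local civil dates, 1900-2100.
#' @param site a [site()] object.
#' @param zenith_deg solar zenith defining the event; default 90.833
#'   (geometric horizon plus standard atmospheric refraction).
#' @return A data.frame with columns `date`, `sunrise`, `sunset` (`POSIXct`,
#'   UTC). On polar day or polar night both events are `NA` — no time is
#'   fabricated.
#' @examples
#' solar_events(as.Date("2016-06-21"), site(55.45, 10.66, 2))
#' @export
solar_events <- function(dates, site, zenith_deg = 90.833) {
  stopifnot(inherits(site, "pam_site"))
  dates <- as.Date(dates)
  yr <- as.integer(format(dates, "%Y"))
  if (any(yr < 1900 | yr > 2100)) stop("dates must lie within 1900-2100")
  # evaluate geometry at local noon of each date
  noon_utc <- parse_utc(dates) + (12 - site$utc_offset) * 3600
  T <- (jd_from_posix(noon_utc) - 2451545) / 36525
  g <- solar_geometry(T)
  latr <- site$latitude * pi / 180
  cos_ha <- cos(zenith_deg * pi / 180) / (cos(latr) * cos(g$declination)) -
    tan(latr) * tan(g$declination)
  polar <- cos_ha < -1 | cos_ha > 1
  ha_deg <- suppressWarnings(acos(pmin(pmax(cos_ha, -1), 1)) * 180 / pi)
  # minutes on the local clock
  noon_min <- 720 - 4 * site$longitude - g$eot_min + site$utc_offset * 60
  sr_min <- noon_min - 4 * ha_deg
  ss_min <- noon_min + 4 * ha_deg
  midnight_utc <- parse_utc(dates) - site$utc_offset * 3600
  sunrise <- midnight_utc + sr_min * MINUTE
  sunset <- midnight_utc + ss_min * MINUTE
  sunrise[polar] <- NA
  sunset[polar] <- NA
  data.frame(date = dates, sunrise = sunrise, sunset = sunset)
}

#' Day length in hours
#' @param dates,site,zenith_deg as in [solar_events()].
#' @return numeric hours; `NA` under polar day/night.
#' @export
day_length <- function(dates, site, zenith_deg = 90.833) {
  ev <- solar_events(dates, site, zenith_deg)
  as.numeric(ev$sunset - ev$sunrise, units = "hours")
}

#' Lunar phase and illumination
#'
#' Phase angle is measured along the mean synodic cycle from new moon
#' (0 = new, pi = full); illumination is the illuminated disc fraction
#' `(1 - cos(phase_angle)) / 2`. The four phase categories quarter the
#' cycle, centred on the cardinal phases (see [lunar_phase_category()]).
#'
#' @param t timestamp vector (`POSIXct` UTC or parseable), 1900-2100.
#' @return data.frame with `illumination` (fraction in \[0, 1\]),
#'   `phase_angle` (radians in \[0, 2*pi)) and `phase_category`
#'   (factor: new, waxing, full, waning).
#' @examples
#' lunar_info(parse_utc("2016-06-20 11:02:00"))  # a catalogued full moon
#' @export
lunar_info <- function(t) {
  t <- parse_utc(t)
  yr <- as.integer(format(t, "%Y"))
  if (any(yr < 1900 | yr > 2100)) stop("timestamps must lie within 1900-2100")
  age <- (jd_from_posix(t) - NEW_MOON_EPOCH_JD) %% SYNODIC_DAYS
  phase_angle <- 2 * pi * age / SYNODIC_DAYS
  illumination <- (1 - cos(phase_angle)) / 2
  data.frame(illumination = illumination,
             phase_angle = phase_angle,
             phase_category = lunar_phase_category(phase_angle))
}

#' Categorise lunar phase angle
#'
#' Quarters the synodic cycle: new = \[7*pi/4, pi/4), waxing = \[pi/4, 3*pi/4),
#' full = \[3*pi/4, 5*pi/4), waning = \[5*pi/4, 7*pi/4). The half-width of the
#' quadrants is configurable through `boundaries`.
#'
#' @param phase_angle radians in \[0, 2*pi).
#' @param boundaries four increasing angles in (0, 2*pi) separating
#'   new|waxing, waxing|full, full|waning, waning|new.
#' @return factor with levels new, waxing, full, waning.
#' @export
lunar_phase_category <- function(phase_angle,
                                 boundaries = c(1, 3, 5, 7) * pi / 4) {
  stopifnot(length(boundaries) == 4L, all(diff(boundaries) > 0))
  idx <- findInterval(phase_angle %% (2 * pi), boundaries)
  lab <- c("new", "waxing", "full", "waning", "new")[idx + 1L]
  factor(lab, levels = c("new", "waxing", "full", "waning"))
}
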