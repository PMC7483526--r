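# Weighted circular statistics on time-of-day angles: mean resultant,
# Rayleigh uniformity test, von Mises maximum likelihood, and a CI for the
# mean direction. Each minute is one angular observation weighted by its
# click count, so clicks act as angular mass over the 24-h circle.

#' Map clock time to an angle on the 24-h circle
#'
#' @param t minutes since midnight in \[0, 1440), an `"HH:MM"` string, or a
#'   `POSIXct` (UTC time of day is used; shift with `utc_offset`).
#' @param utc_offset hours added before taking the time of day (only used
#'   for `POSIXct` input).
#' @return radians in \[0, 2*pi): `2 * pi * minutes / 1440`.
#' @examples
#' time_to_angle("12:00")  # pi
#' @export
time_to_angle <- function(t, utc_offset = 0) {
  m <- if (inherits(t, "POSIXct")) {
    local_minute_of_day(t, utc_offset)
  } else if (is.character(t)) {
    parts <- strsplit(t, ":", fixed = TRUE)
    vapply(parts, function(p) as.numeric(p[1L]) * 60 + as.numeric(p[2L]),
           numeric(1))
  } else {
    as.numeric(t)
  }
  if (any(m < 0 | m >= 1440)) stop("time of day must lie in [00:00, 24:00)")
  2 * pi * m / 1440
}

#' Format an angle (and optional CI) as local clock time
#'
#' @param theta radians; interpreted on the 24-h circle.
#' @param ci optional length-2 radians vector (lower, upper along the circle
#'   through `theta`); a CI straddling midnight renders with wrapped
#'   endpoints, e.g. `23:50` to `00:09`.
#' @param utc_offset hours added when formatting (fixed offset, no DST).
#' @return `"HH:MM"` string, or named vector `c(time, ci_lower, ci_upper)`.
#' @export
angle_to_clock <- function(theta, ci = NULL, utc_offset = 0) {
  fmt <- function(a) {
    m <- round((a / (2 * pi) * 1440 + utc_offset * 60)) %% 1440
    sprintf("%02d:%02d", m %/% 60, m %% 60)
  }
  if (is.null(ci)) return(fmt(theta))
  c(time = fmt(theta), ci_lower = fmt(ci[1L]), ci_upper = fmt(ci[2L]))
}

#' Weighted mean resultant of a circular sample
#'
#' @param angles radians in \[0, 2*pi).
#' @param weights non-negative weights (default 1 per angle); with click
#'   counts as weights each minute contributes its click mass.
#' @return list with `mu` (mean direction, radians in \[0, 2*pi); `NA` when
#'   `r_bar` is 0, where the direction is undefined) and `r_bar` (mean
#'   resultant length in \[0, 1\]).
#' @export
mean_resultant <- function(angles, weights = NULL) {
  w <- check_angles(angles, weights)
  C <- sum(w * cos(angles)) / sum(w)
  S <- sum(w * sin(angles)) / sum(w)
  r_bar <- sqrt(C^2 + S^2)
  mu <- if (r_bar < 1e-15) NA_real_ else atan2(S, C) %% (2 * pi)
  list(mu = mu, r_bar = min(r_bar, 1))
}

check_angles <- function(angles, weights) {
  if (any(!is.finite(angles)) || any(angles < 0 | angles >= 2 * pi)) {
    stop("angles must be finite radians in [0, 2*pi)")
  }
  w <- if (is.null(weights)) rep(1, length(angles)) else weights
  if (length(w) != length(angles)) stop("weights length must match angles")
  if (any(w < 0) || any(!is.finite(w))) stop("weights must be non-negative")
  if (sum(w) <= 0) stop("effective sample size is zero (all weights zero)")
  w
}

effective_n <- function(weights, neff_mode) {
  switch(neff_mode,
         weights = sum(weights),
         minutes = sum(weights > 0),
         stop("neff_mode must be 'weights' or 'minutes'"))
}

#' Rayleigh test of circular uniformity
#'
#' Tests departure from a uniform (non-directional) distribution of angular
#' mass. The statistic is the mean resultant length; the p-value uses the
#' standard large-sample approximation
#' `p = exp(sqrt(1 + 4n + 4n^2(1 - rbar^2)) - (1 + 2n))`.
#'
#' The effective sample size for weighted data is not settled:
#' `neff_mode = "weights"` (default) uses the summed weights (total clicks),
#' `"minutes"` the number of nonzero-weight minutes — clicks within a minute
#' are not independent, so `"minutes"` is the conservative choice.
#'
#' @param angles,weights as in [mean_resultant()].
#' @param neff_mode `"weights"` or `"minutes"`.
#' @return list of class `"rayleigh_result"`: `r_bar`, `p_value`, `n_eff`,
#'   `neff_mode`.
#' @export
rayleigh_test <- function(angles, weights = NULL, neff_mode = "weights") {
  w <- check_angles(angles, weights)
  n <- effective_n(w, neff_mode)
  if (n < 3) stop("effective sample size must be at least 3")
  r_bar <- mean_resultant(angles, w)$r_bar
  p <- exp(sqrt(1 + 4 * n + 4 * n^2 * (1 - r_bar^2)) - (1 + 2 * n))
  structure(list(r_bar = r_bar, p_value = min(max(p, 0), 1),
                 n_eff = n, neff_mode = neff_mode),
            class = "rayleigh_result")
}

#' @export
print.rayleigh_result <- function(x, ...) {
  cat(sprintf("<Rayleigh test: r_bar = %.3f, p = %.3g (n_eff = %.0f, %s)>\n",
              x$r_bar, x$p_value, x$n_eff, x$neff_mode))
  invisible(x)
}

# A1(kappa) = I1(kappa) / I0(kappa); the exponential scaling cancels, which
# keeps the ratio finite for large kappa
vm_a1 <- function(kappa) {
  besselI(kappa, 1, expon.scaled = TRUE) / besselI(kappa, 0, expon.scaled = TRUE)
}

# invert A1 by bracketed root finding; A1 is strictly increasing with
# A1(0) = 0 and A1 -> 1
vm_a1inv <- function(r, tol = 1e-10) {
  stopifnot(r >= 0, r < 1)
  if (r == 0) return(0)
  hi <- 1
  while (vm_a1(hi) < r) hi <- hi * 2
  stats::uniroot(function(k) vm_a1(k) - r, c(0, hi), tol = tol)$root
}

#' Von Mises maximum-likelihood fit with a CI for the mean direction
#'
#' Fits a von Mises ("circular normal") distribution by maximum likelihood:
#' the mean direction is the weighted mean-resultant direction; the
#' concentration solves `A1(kappa) = r_bar` with `A1 = I1/I0` (modified
#' Bessel ratio), by bracketed root finding to `|A1(kappa) - r_bar| < 1e-8`.
#' The CI for the mean direction is the asymptotic normal interval
#' `mu +/- z * 1 / sqrt(n_eff * r_bar * kappa)`; see
#' [vonmises_bootstrap_ci()] for a resampling cross-check.
#'
#' @param angles,weights as in [mean_resultant()].
#' @param conf confidence level (default 0.95).
#' @param neff_mode `"weights"` (summed weights, default) or `"minutes"`.
#' @param bias_correct apply the standard small-sample correction to kappa
#'   (off by default).
#' @return object of class `"circular_fit"`: `mu`, `kappa`, `r_bar`,
#'   `n_eff`, `ci_mu` (lower, upper radians along the circle through `mu`,
#'   possibly outside \[0, 2*pi) so the interval stays connected), `conf`,
#'   `se`, `neff_mode`.
#' @examples
#' th <- rvonmises(500, pi / 2, 4, seed = 1)
#' fit_vonmises(th)
#' @export
fit_vonmises <- function(angles, weights = NULL, conf = 0.95,
                         neff_mode = "weights", bias_correct = FALSE) {
  w <- check_angles(angles, weights)
  n <- effective_n(w, neff_mode)
  if (n < 3) stop("effective sample size must be at least 3")
  mr <- mean_resultant(angles, w)
  if (mr$r_bar < 1e-15) stop("mean resultant length is zero: no fit exists")
  r <- mr$r_bar
  if (r >= 1 - 1e-12) {
    warning("resultant length at the point-mass limit; kappa capped")
    kappa <- 1 / (2 * (1 - min(r, 1 - 1e-12)))
  } else {
    kappa <- vm_a1inv(r)
  }
  if (bias_correct) {
    m <- sum(w > 0)
    kappa <- if (kappa < 2) max(kappa - 2 / (m * kappa), 0) else
      kappa * (m - 1)^3 / (m^3 + m)
  }
  se <- 1 / sqrt(n * r * kappa)
  z <- stats::qnorm((1 + conf) / 2)
  structure(list(mu = mr$mu, kappa = kappa, r_bar = r, n_eff = n,
                 ci_mu = c(mr$mu - z * se, mr$mu + z * se),
                 conf = conf, se = se, neff_mode = neff_mode),
            class = "circular_fit")
}

#' @export
print.circular_fit <- function(x, ...) {
  ck <- angle_to_clock(x$mu, x$ci_mu)
  cat(sprintf(
    "<von Mises fit: mu = %.4f rad (%s), kappa = %.3f, r_bar = %.3f, n_eff = %.0f\n %d%% CI for mu: (%s, %s)>\n",
    x$mu, ck[["time"]], x$kappa, x$r_bar, x$n_eff, round(100 * x$conf),
    ck[["ci_lower"]], ck[["ci_upper"]]))
  invisible(x)
}

#' Bootstrap CI for the von Mises mean direction
#'
#' Resamples observations (minutes) with replacement, refits the mean
#' direction, and forms a percentile interval on the circular deviations
#' from the point estimate — a cross-check on the asymptotic CI of
#' [fit_vonmises()].
#'
#' @param angles,weights as in [mean_resultant()].
#' @param conf confidence level.
#' @param n_boot bootstrap replicates.
#' @param seed integer seed.
#' @return length-2 vector (lower, upper radians along the circle).
#' @export
vonmises_bootstrap_ci <- function(angles, weights = NULL, conf = 0.95,
                                  n_boot = 500, seed = NULL) {
  w <- check_angles(angles, weights)
  mu_hat <- mean_resultant(angles, w)$mu
  if (!is.null(seed)) set.seed(seed)
  n <- length(angles)
  dev <- vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(n, n, replace = TRUE)
    mu_b <- mean_resultant(angles[idx], w[idx])$mu
    ((mu_b - mu_hat + pi) %% (2 * pi)) - pi
  }, numeric(1))
  q <- stats::quantile(dev, c((1 - conf) / 2, (1 + conf) / 2), names = FALSE)
  mu_hat + q
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher acceptance-rejection sampler; `kappa = 0` reduces to the
#' circular uniform.
#'
#' @param n number of draws.
#' @param mu mean direction (radians).
#' @param kappa concentration (>= 0).
#' @param seed optional integer seed.
#' @return radians in \[0, 2*pi).
#' @export
rvonmises <- function(n, mu, kappa, seed = NULL) {
  stopifnot(kappa >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (kappa == 0) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    theta <- sign(u3 - 0.5) * acos(f)
    acc <- theta[ok]
    take <- min(length(acc), n - got)
    if (take > 0L) out[(got + 1L):(got + take)] <- acc[seq_len(take)]
    got <- got + take
  }
  (out + mu) %% (2 * pi)
}
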