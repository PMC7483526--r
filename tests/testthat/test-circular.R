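test_that("clock time maps to the expected angles", {
  expect_equal(time_to_angle("00:00"), 0)
  expect_equal(time_to_angle("12:00"), pi)
  expect_equal(time_to_angle("23:59"), 2 * pi * 1439 / 1440)
  expect_equal(time_to_angle(parse_utc("2016-06-06 06:00:00")), pi / 2)
  expect_error(time_to_angle(1441), "time of day")
})

test_that("angles format back to clock times, with CI wrap across midnight", {
  expect_equal(angle_to_clock(0), "00:00")
  expect_equal(angle_to_clock(pi), "12:00")
  # CI straddling midnight keeps wrapped endpoints in order along the circle
  mu <- time_to_angle("23:59")
  ci <- mu + c(-9, 10) * 2 * pi / 1440
  out <- angle_to_clock(mu, ci)
  expect_equal(unname(out), c("23:59", "23:50", "00:09"))
  # fixed local offset applies to all three
  out2 <- angle_to_clock(0, c(-pi / 144, pi / 144), utc_offset = 2)
  expect_equal(unname(out2), c("02:00", "01:55", "02:05"))
})

test_that("mean resultant honours symmetry, point mass and cancellation", {
  th <- time_to_angle(c("23:00", "01:00"))
  mr <- mean_resultant(th)
  expect_true(min(mr$mu, 2 * pi - mr$mu) < 1e-9)  # midnight
  expect_equal(mean_resultant(rep(pi / 3, 5))$r_bar, 1)
  mr0 <- mean_resultant(c(0, pi / 2, pi, 3 * pi / 2))
  expect_lt(mr0$r_bar, 1e-12)
  expect_true(is.na(mr0$mu))
})

test_that("weight scaling leaves mu, r_bar and kappa unchanged", {
  set.seed(71)
  th <- rvonmises(200, 1.3, 2)
  w <- rpois(200, 5) + 1
  f1 <- fit_vonmises(th, w)
  f2 <- fit_vonmises(th, w * 7)
  expect_equal(f1$mu, f2$mu)
  expect_equal(f1$r_bar, f2$r_bar)
  expect_equal(f1$kappa, f2$kappa)
  # n_eff convention differs by design between modes
  expect_equal(fit_vonmises(th, w, neff_mode = "minutes")$n_eff, 200)
})

test_that("rotation equivariance: shifting all angles shifts mu and CI, fixes r_bar/kappa/p", {
  set.seed(72)
  th <- rvonmises(300, 0.8, 3)
  w <- rpois(300, 3) + 1
  delta <- 1.234
  f1 <- fit_vonmises(th, w)
  f2 <- fit_vonmises((th + delta) %% (2 * pi), w)
  expect_equal((f2$mu - f1$mu) %% (2 * pi), delta, tolerance = 1e-8)
  expect_equal(f1$r_bar, f2$r_bar)
  expect_equal(f1$kappa, f2$kappa)
  expect_equal(diff(f1$ci_mu), diff(f2$ci_mu))
  r1 <- rayleigh_test(th, w); r2 <- rayleigh_test((th + delta) %% (2 * pi), w)
  expect_equal(r1$p_value, r2$p_value)
})

test_that("Rayleigh p is tiny for a point mass and the test validates inputs", {
  r <- rayleigh_test(rep(2, 50))
  expect_equal(r$r_bar, 1)
  expect_lt(r$p_value, 1e-10)
  expect_error(rayleigh_test(c(0, 1)), "at least 3")
})

test_that("Rayleigh p-values are approximately uniform under uniform angles", {
  set.seed(73)
  ps <- replicate(300, rayleigh_test(runif(200, 0, 2 * pi))$p_value)
  expect_lt(suppressWarnings(ks.test(ps, "punif")$statistic), 0.08)
})

test_that("A1 inversion matches a Bessel-quadrature grid oracle to 1e-6", {
  # oracle: A1 via numerical integral representation of I0, I1, inverted on
  # a fine kappa grid — independent of the package's besselI route
  a1_quad <- function(k) {
    i0 <- integrate(function(x) exp(k * cos(x)) / pi, 0, pi,
                    rel.tol = 1e-12)$value
    i1 <- integrate(function(x) exp(k * cos(x)) * cos(x) / pi, 0, pi,
                    rel.tol = 1e-12)$value
    i1 / i0
  }
  coarse <- seq(1e-4, 12, by = 0.01)
  a1_coarse <- vapply(coarse, a1_quad, numeric(1))
  for (r in seq(0.05, 0.95, by = 0.1)) {
    kappa_hat <- dielPAM:::vm_a1inv(r)
    # oracle inversion: coarse bracket, then a fine local quadrature grid
    j <- findInterval(r, a1_coarse)
    fine <- seq(coarse[j], coarse[j + 1], length.out = 400)
    a1_fine <- vapply(fine, a1_quad, numeric(1))
    i <- findInterval(r, a1_fine)
    kappa_oracle <- fine[i] + (r - a1_fine[i]) /
      (a1_fine[i + 1] - a1_fine[i]) * (fine[i + 1] - fine[i])
    expect_lt(abs(kappa_hat - kappa_oracle), 1e-6)
    expect_lt(abs(dielPAM:::vm_a1(kappa_hat) - r), 1e-8)
  }
})

test_that("A1 is strictly increasing from 0 towards 1", {
  ks <- seq(0, 50, by = 0.25)
  a1 <- dielPAM:::vm_a1(ks)
  expect_equal(a1[1], 0)
  expect_true(all(diff(a1) > 0))
  expect_gt(a1[length(a1)], 0.98)
})

test_that("von Mises fit recovers the generating direction and concentration", {
  set.seed(74)
  th <- rvonmises(2000, pi / 2, 4)
  f <- fit_vonmises(th)
  expect_lt(abs(f$mu - pi / 2), 0.05)
  expect_lt(abs(f$kappa - 4), 0.5)
  # uniform limit: kappa near zero
  fu <- fit_vonmises(runif(5000, 0, 2 * pi))
  expect_lt(fu$kappa, 0.1)
  # near point mass: kappa capped with warning
  expect_warning(fit_vonmises(rep(1, 10) + c(rep(0, 9), 1e-14)), "capped")
})

test_that("asymptotic and bootstrap CIs for the mean direction agree in width", {
  set.seed(75)
  th <- rvonmises(500, 2, 3)
  f <- fit_vonmises(th)
  bci <- vonmises_bootstrap_ci(th, n_boot = 400, seed = 8)
  expect_lt(abs(diff(bci) - diff(f$ci_mu)) / diff(f$ci_mu), 0.35)
  expect_true(f$ci_mu[1] < f$mu && f$mu < f$ci_mu[2])
})

test_that("von Mises sampler produces the right first trigonometric moment", {
  th <- rvonmises(20000, 1, 2.5, seed = 76)
  mr <- mean_resultant(th)
  expect_lt(abs(mr$mu - 1), 0.03)
  expect_lt(abs(mr$r_bar - dielPAM:::vm_a1(2.5)), 0.02)
  expect_true(all(th >= 0 & th < 2 * pi))
})
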